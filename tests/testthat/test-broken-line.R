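test_that("broken-line prediction is continuous and plateaus exactly at L", {
  ox <- bl_params("LBL", L = 75.77, U = -0.07, R = 82)
  expect_equal(bl_predict(ox, 100), 75.77)            # above the break
  expect_equal(bl_predict(ox, 82), 75.77)             # at the break
  expect_equal(bl_predict(ox, 10.4), 75.77 - 0.07 * (82 - 10.4))
  su <- bl_params("QBL", L = 78.17, U = -0.009, R = 40)
  expect_equal(bl_predict(su, 10.4), 78.17 - 0.009 * 29.6^2)  # 70.28
  expect_equal(bl_predict(su, 40), 78.17)
  expect_equal(bl_predict(su, 70.7), 78.17)
  # QBL join is smooth: derivative ~ 0 just below the break
  eps <- 1e-6
  expect_lt(abs(bl_predict(su, 40 - eps) - bl_predict(su, 40)) / eps, 1e-4)
})

test_that("noise-free LBL data are recovered exactly", {
  truth <- bl_params("LBL", L = 75.77, U = -0.07, R = 82)
  X <- c(10.4, 40.20, 70.75, 100.60)
  f <- bl_fit(X, bl_predict(truth, X), "LBL")
  expect_equal(f$params$R, 82, tolerance = 1e-6)
  expect_equal(f$params$L, 75.77, tolerance = 1e-6)
  expect_equal(f$params$U, -0.07, tolerance = 1e-6)
  expect_lt(f$quality$SSE, 1e-12)
  expect_false(f$flags$flat_profile)
})

test_that("noise-free QBL data with three sub-plateau doses are recovered exactly", {
  truth <- bl_params("QBL", L = 78.17, U = -0.009, R = 40)
  X <- c(10, 20, 30, 55)   # three doses below the break pin the parabola
  f <- bl_fit(X, bl_predict(truth, X), "QBL")
  expect_equal(f$params$R, 40, tolerance = 1e-5)
  expect_equal(f$params$L, 78.17, tolerance = 1e-6)
  expect_equal(f$params$U, -0.009, tolerance = 1e-6)
})

test_that("a single sub-plateau dose leaves the QBL break unidentified and is flagged", {
  truth <- bl_params("QBL", L = 78.17, U = -0.009, R = 40)
  X <- c(10.4, 40.25, 70.70, 100.25)  # only 10.4 lies below the break
  f <- bl_fit(X, bl_predict(truth, X), "QBL")
  expect_true(f$flags$flat_profile)
  # the reported break is the supremum of the SSE-minimising set: the
  # smallest dose on the plateau
  expect_lt(abs(f$params$R - 40.25), 0.05)
  expect_lt(f$quality$SSE, 1e-9)
})

test_that("flat responses and short data degenerate cleanly", {
  f <- bl_fit(c(1, 2, 3, 4), rep(5, 4), "LBL")
  expect_true(f$flags$degenerate)
  expect_equal(f$params$U, 0)
  expect_true(is.na(f$params$R))
  expect_equal(f$quality$R2, 0)
  expect_error(bl_fit(c(1, 2, 3), c(1, 2, 3), "LBL"), "identifiability")
  expect_error(bl_fit(c(1, 1, 2, 2), c(1, 1, 2, 2), "LBL"), "identifiability")
})

test_that("fit-quality criteria follow their closed forms and a summation oracle", {
  # N = 4, SSE = 4, P = 2 -> AIC = 4 ln(1) + 4 = 4
  q <- fit_quality(c(0, 0, 2, 2), c(1, 1, 1, 1), k = 1)
  expect_equal(q$SSE, 4)
  expect_equal(q$AIC, 4)
  expect_equal(q$RMSE, 1)
  # perfect fit
  qp <- fit_quality(c(1, 2, 3, 4), c(1, 2, 3, 4), k = 3)
  expect_equal(qp$R2, 1)
  expect_equal(qp$RMSE, 0)
  expect_true(is.infinite(qp$AIC) && qp$AIC < 0)
  expect_true(qp$perfect_fit)
  # 10-point fit vs direct sums
  set.seed(5)
  y <- rnorm(10); yhat <- y + rnorm(10, 0, 0.3)
  q10 <- fit_quality(y, yhat, k = 3)
  sse <- sum((y - yhat)^2); sst <- sum((y - mean(y))^2)
  expect_equal(q10$SSE, sse, tolerance = 1e-10)
  expect_equal(q10$R2, (sst - sse) / sst, tolerance = 1e-10)
  expect_equal(q10$adj_R2, 1 - (1 - q10$R2) * 9 / (10 - 4), tolerance = 1e-10)
  expect_equal(q10$RMSE, sqrt(sse / 10), tolerance = 1e-10)
  expect_equal(q10$AIC, 10 * log(sse / 10) + 2 * 4, tolerance = 1e-10)
})

test_that("the fitted broken line always nests the constant model", {
  set.seed(17)
  for (i in 1:20) {
    X <- sort(runif(12, 0, 100))
    Y <- 70 + 0.1 * pmin(X, 60) + rnorm(12, 0, 3)
    f <- bl_fit(X, Y, sample(c("LBL", "QBL"), 1))
    expect_lte(f$quality$SSE, sum((Y - mean(Y))^2) + 1e-9)
  }
})

test_that("model selection prefers the generating form and is stable under ties", {
  X <- rep(c(10, 25, 40, 60, 90), each = 6)
  # data generated exactly from one form: that form fits perfectly, the
  # other cannot, so the generating form always ranks first
  for (form in c("LBL", "QBL")) {
    truth <- bl_params(form, L = 78, U = if (form == "QBL") -0.009 else -0.3,
                       R = 45)
    Y <- bl_predict(truth, X)
    fits <- list(LBL = bl_fit(X, Y, "LBL"), QBL = bl_fit(X, Y, "QBL"))
    sel <- select_model(fits)
    expect_equal(sel$best$params$form, form)
    expect_gt(sel$table$SSE[2], sel$table$SSE[1])
    expect_named(sel$table, c("model", "form", "L", "U", "R", "SSE", "R2",
                              "adj_R2", "RMSE", "AIC"))
  }
  # noisy data: the ranking is a permutation with a coherent criterion table
  set.seed(29)
  Yn <- bl_predict(bl_params("LBL", 78, -0.3, 45), X) + rnorm(length(X), 0, 1.5)
  seln <- select_model(list(bl_fit(X, Yn, "LBL"), bl_fit(X, Yn, "QBL")))
  expect_setequal(seln$ranking, 1:2)
  # identical candidates keep their input order
  f <- bl_fit(X, Yn, "LBL")
  expect_equal(select_model(list(f, f))$ranking, c(1, 2))
  # different data refuse to be compared
  f2 <- bl_fit(X + 1, Yn, "LBL")
  expect_error(select_model(list(f, f2)), "comparison")
})

test_that("stochastic break-point recovery matches the generative model", {
  # oxide-arm generative model, replicate noise, moderate seed count
  truth <- bl_params("LBL", L = 75.77, U = -0.07, R = 82)
  X <- rep(c(10.4, 40.20, 70.75, 100.60), each = 6)
  set.seed(2024)
  Rhat <- replicate(120, {
    Y <- bl_predict(truth, X) + rnorm(length(X), 0, 4.1)
    bl_fit(X, Y, "LBL")$params$R
  })
  expect_lt(abs(mean(Rhat) - 82), 10)
  expect_gt(sd(Rhat), 18.5 / 2)
  expect_lt(sd(Rhat), 18.5 * 2)
})
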