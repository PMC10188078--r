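test_that("dose encoding is one-hot by source with an all-zero control", {
  d <- mn_reference_design()
  enc <- encode_doses(d)
  expect_equal(names(enc), c("treatment", "oxide", "sulphate", "organic"))
  expect_equal(unlist(enc[1, -1], use.names = FALSE), c(0, 0, 0))
  # sulphate at nominal 60 -> (0, 60, 0)
  i60 <- which(d$treatments$source == "sulphate" &
                 d$treatments$nominal_level == 60)
  expect_equal(unlist(enc[i60, -1], use.names = FALSE), c(0, 60, 0))
  expect_true(all(rowSums(enc[, -1] > 0) <= 1))
  # analysed scale subtracts the control's analysed concentration
  enc_a <- encode_doses(d, "supplemental_analyzed")
  i_top <- which(d$treatments$source == "sulphate" &
                   d$treatments$nominal_level == 90)
  expect_equal(enc_a$sulphate[i_top], 100.25 - 10.4)
})

test_that("OLS recovers known coefficients exactly and matches the normal equations", {
  d <- mn_reference_design()
  enc <- encode_doses(d)
  X <- as.matrix(enc[, -1])
  a <- 72.5; b <- c(oxide = 0.035, sulphate = 0.068, organic = 0.079)
  # noise-free treatment means -> exact interpolation
  y0 <- a + X %*% b
  f0 <- fit_slope_ratio(as.numeric(y0), enc)
  expect_equal(unname(f0$coefficients),
               unname(c(a, b)), tolerance = 1e-10)
  # equal true slopes collapse to a single common slope
  yeq <- 10 + 0.05 * rowSums(X)
  feq <- fit_slope_ratio(yeq, enc)
  expect_equal(unname(feq$coefficients[-1]), rep(0.05, 3), tolerance = 1e-10)
  # noisy replicate-level fit vs brute-force normal-equation solve
  set.seed(55)
  Xrep <- X[rep(1:10, each = 6), ]
  yrep <- as.numeric(a + Xrep %*% b) + rnorm(60, 0, 2)
  f <- fit_slope_ratio(yrep, as.data.frame(Xrep))
  M <- cbind(1, Xrep)
  beta <- solve(t(M) %*% M, t(M) %*% yrep)
  expect_equal(unname(f$coefficients), as.numeric(beta), tolerance = 1e-10)
})

test_that("replicate-level and treatment-mean fits agree under equal replication", {
  d <- mn_reference_design()
  enc <- encode_doses(d)
  X <- as.matrix(enc[, -1])
  set.seed(8)
  Xrep <- X[rep(1:10, each = 6), ]
  yrep <- as.numeric(72 + Xrep %*% c(0.03, 0.07, 0.08)) + rnorm(60, 0, 3)
  ymean <- tapply(yrep, rep(1:10, each = 6), mean)
  f_rep <- fit_slope_ratio(yrep, as.data.frame(Xrep))
  f_mean <- fit_slope_ratio(as.numeric(ymean), enc)
  expect_equal(f_rep$coefficients, f_mean$coefficients, tolerance = 1e-10)
})

test_that("rank-deficient or degenerate encodings raise identifiability errors", {
  d <- mn_reference_design()
  enc <- encode_doses(d)
  dup <- enc; dup$copy <- dup$oxide
  expect_error(fit_slope_ratio(rnorm(10), dup), "identifiability")
  zero <- enc; zero$organic <- 0
  expect_error(fit_slope_ratio(rnorm(10), zero), "identifiability")
})

test_that("RBE is the slope ratio, invariant to dose rescaling, 100% for the reference", {
  d <- mn_reference_design()
  enc <- encode_doses(d)
  X <- as.matrix(enc[, -1])
  set.seed(91)
  Xrep <- X[rep(1:10, each = 6), ]
  yrep <- as.numeric(72 + Xrep %*% c(0.03, 0.07, 0.08)) + rnorm(60, 0, 2)
  f <- fit_slope_ratio(yrep, as.data.frame(Xrep))
  r <- rbe(f, reference = "organic")
  tab <- r$table
  expect_equal(tab$rbe[tab$source == "organic"], 100)
  b <- f$coefficients[f$sources]
  expect_equal(tab$rbe[tab$source == "oxide"],
               100 * unname(b["oxide"] / b["organic"]), tolerance = 1e-12)
  # rescaling all dose columns by c rescales slopes by 1/c, RBE unchanged
  f2 <- fit_slope_ratio(yrep, as.data.frame(Xrep * 2))
  expect_equal(unname(f2$coefficients[-1]),
               unname(f$coefficients[-1]) / 2, tolerance = 1e-10)
  r2 <- rbe(f2, reference = "organic")
  expect_equal(r2$table$rbe, tab$rbe, tolerance = 1e-9)
  # Fieller interval contains the point estimate and brackets the delta one
  ox <- tab[tab$source == "oxide", ]
  expect_true(ox$fieller_lo < ox$rbe && ox$rbe < ox$fieller_hi)
  expect_true(ox$delta_lo < ox$rbe && ox$rbe < ox$delta_hi)
})

test_that("a near-zero reference slope makes RBE undefined", {
  f <- as_slope_ratio_fit(70, c(oxide = 0.03, organic = 0))
  expect_error(rbe(f, reference = "organic"), "undefined")
  # equal printed slopes give exactly 100%
  g <- as_slope_ratio_fit(2.52, c(sulphate = -0.0025, organic = -0.0025))
  expect_equal(rbe(g, "organic")$table$rbe_rounded[1], 100L)
})
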