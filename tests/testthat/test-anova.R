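test_that("one-way ANOVA matches the direct sums-of-squares oracle", {
  set.seed(101)
  g <- rep(1:10, each = 6)
  mu <- seq(70, 79, length.out = 10)
  y <- mu[g] + rnorm(60, 0, 4)
  d <- data.frame(treatment = g, y = y)
  res <- one_way_anova(d, "y")
  orc <- anova_ss_oracle(y, g)
  expect_equal(res$F, orc$F, tolerance = 1e-10)
  expect_equal(res$MSE, orc$mse, tolerance = 1e-10)
  expect_equal(res$df, orc$dfw)
  expect_equal(res$SEM, sqrt(orc$mse / 6), tolerance = 1e-12)
  # decomposition: SS_total = SS_treatment + SS_error
  expect_equal(orc$ssb + orc$ssw, sum((y - mean(y))^2), tolerance = 1e-9)
})

test_that("degenerate and two-group layouts behave classically", {
  d0 <- data.frame(treatment = rep(1:3, each = 4), y = 5)
  r0 <- one_way_anova(d0, "y")
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  expect_true(all(r0$means$letter == "a"))

  set.seed(7)
  d2 <- data.frame(treatment = rep(c("A", "B"), each = 8),
                   y = rnorm(16) + rep(c(0, 1), each = 8))
  r2 <- one_way_anova(d2, "y")
  tt <- t.test(y ~ treatment, data = d2, var.equal = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey letters separate exactly the pairs beyond the HSD", {
  k <- 3; r <- 6; df <- 15; mse <- 4
  hsd <- qtukey(0.95, k, df) * sqrt(mse / r)
  expect_equal(tukey_cld(c(5, 5, 5), mse, df, r), c("a", "a", "a"))
  far <- tukey_cld(c(0, 10 * hsd, 20 * hsd), mse, df, r)
  expect_equal(far, c("a", "b", "c"))
  # chain pattern: A ~ B, B ~ C, A != C -> middle mean carries both letters
  chain <- tukey_cld(c(0, 0.9 * hsd, 1.8 * hsd), mse, df, r)
  expect_equal(chain, c("a", "ab", "b"))
})

test_that("Tukey letter structure is invariant under treatment relabeling", {
  set.seed(21)
  m <- c(70, 71, 75, 80, 80.5)
  mse <- 3; df <- 25; r <- 6
  l1 <- tukey_cld(m, mse, df, r)
  perm <- c(3, 1, 5, 2, 4)
  l2 <- tukey_cld(m[perm], mse, df, r)
  # same grouping structure: i, j share a letter before iff they do after
  share <- function(l) outer(l, l, Vectorize(function(a, b)
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  expect_equal(unname(share(l2)), unname(share(l1)[perm, perm]))
})

test_that("letters agree with multcomp's Tukey grouping on a realistic table", {
  skip_if_not_installed("multcomp")
  set.seed(33)
  g <- factor(rep(letters[1:6], each = 6))
  y <- rep(c(70, 74, 74.5, 78, 78.2, 83), each = 6) + rnorm(36, 0, 2)
  res <- one_way_anova(data.frame(treatment = g, y = y), "y")
  fit <- aov(y ~ g)
  cld_ref <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")))
  share <- function(l) outer(l, l, Vectorize(function(a, b)
    any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])))
  expect_equal(unname(share(res$means$letter)),
               unname(share(unname(cld_ref$mcletters$Letters))))
})

test_that("orthogonal polynomial contrasts reproduce classical and Gram-Schmidt forms", {
  # equally spaced: linear coefficients proportional to (-3, -1, 1, 3)
  pc <- poly_dose_contrasts(c(1, 2, 3, 4), c(0, 30, 60, 90),
                            MSE = 1, df = 20, r = 6)
  cf <- attr(pc, "coefficients")
  expect_equal(cf[, "linear"] / cf[4, "linear"] * 3, c(-3, -1, 1, 3),
               tolerance = 1e-12)
  # means exactly linear in dose -> quadratic estimate is zero
  doses <- c(10.4, 40.2, 70.75, 100.6)
  lin_means <- 2 + 0.05 * doses
  pc2 <- poly_dose_contrasts(lin_means, doses, MSE = 1, df = 20, r = 6)
  expect_equal(pc2$estimate[pc2$contrast == "quadratic"], 0,
               tolerance = 1e-12)
  # unequal spacing: matches an independent Gram-Schmidt construction
  cf2 <- attr(pc2, "coefficients")
  gs <- gram_schmidt_contrasts(doses)
  for (j in 1:2) {
    expect_equal(abs(cf2[, j]), abs(gs[, j]), tolerance = 1e-10)
    expect_lt(abs(sum(cf2[, j])), 1e-12)              # zero-sum
  }
  expect_lt(abs(sum(cf2[, 1] * cf2[, 2])), 1e-12)     # orthogonal
})

test_that("per-source dose-response summary shares the control and pools the error", {
  d <- toy_design()
  truth <- list(ep = trait_truth(bl_params("LBL", 75, -0.1, 60), noise_sd = 2))
  reps <- simulate_replicates(d, truth, seed = 13)
  tt <- compute_traits(reps)
  dr <- dose_response_anova(tt, d, "EP")
  expect_equal(dr$period, "overall")
  expect_setequal(unique(dr$contrasts$source), c("oxide", "sulphate"))
  # 3 doses per arm (control + 2 levels) -> linear and quadratic rows
  expect_equal(nrow(dr$contrasts), 4L)
  expect_true(all(dr$contrasts$p >= 0 & dr$contrasts$p <= 1))
})
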