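# Shared fixtures, all built in code.

# small two-source design with analysed concentrations, used across tests
toy_design <- function() {
  trial_design(
    treatments = data.frame(
      source = c("none", "oxide", "oxide", "sulphate", "sulphate"),
      supplement_rate = c(0, 43, 86, 82, 164),
      mn_fraction = c(NA, 0.6962, 0.6962, 0.364, 0.364),
      analyzed_total_mn = c(10.4, 40.2, 70.75, 40.25, 70.7)
    ),
    basal_mn = 10.3, n_replicates = 3, birds_per_replicate = 4,
    n_periods = 2, period_days = 28
  )
}

# independent sums-of-squares oracle for a one-way layout
anova_ss_oracle <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  n_i <- tapply(y, g, length)
  ssb <- sum(n_i * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  dfb <- nlevels(g) - 1
  dfw <- length(y) - nlevels(g)
  list(ssb = ssb, ssw = ssw, F = (ssb / dfb) / (ssw / dfw),
       mse = ssw / dfw, dfw = dfw)
}

# independent Gram-Schmidt orthogonalisation of (1, x, x^2)
gram_schmidt_contrasts <- function(x) {
  v0 <- rep(1, length(x))
  v1 <- x - sum(x * v0) / sum(v0 * v0) * v0
  v2 <- x^2 - sum(x^2 * v0) / sum(v0 * v0) * v0 -
    sum(x^2 * v1) / sum(v1 * v1) * v1
  cbind(linear = v1 / sqrt(sum(v1^2)), quadratic = v2 / sqrt(sum(v2^2)))
}

# brute-force profiled broken-line SSE on a fixed grid
profile_sse_oracle <- function(X, Y, form, grid) {
  p <- if (form == "QBL") 2 else 1
  vapply(grid, function(r) {
    z <- (r - X)^p * (X < r)
    if (all(z == 0)) return(sum((Y - mean(Y))^2))
    sum(stats::lsfit(z, Y)$residuals^2)
  }, numeric(1))
}
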