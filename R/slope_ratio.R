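#' Per-source dose columns for the slope-ratio model
#'
#' Encodes each treatment's supplemental dose into one column per source
#' (one-hot by source): the control row is all-zero and every supplemented
#' treatment has a single nonzero entry. `"supplemental_nominal"` uses the
#' design's added-Mn labels (e.g. 0/30/60/90); `"supplemental_analyzed"`
#' uses analysed total Mn minus the control's analysed concentration.
#'
#' @param design a [trial_design()].
#' @param dose_scale `"supplemental_nominal"` (default) or
#'   `"supplemental_analyzed"`.
#' @return data frame with one row per treatment: `treatment` plus one dose
#'   column per source (in design order).
#' @export
encode_doses <- function(design,
                         dose_scale = c("supplemental_nominal",
                                        "supplemental_analyzed")) {
  dose_scale <- match.arg(dose_scale)
  stopifnot(inherits(design, "trial_design"))
  tr <- design$treatments
  if (sum(tr$source == "none") != 1L) {
    stop("invalid-design: exactly one control treatment required", call. = FALSE)
  }
  srcs <- setdiff(unique(tr$source), "none")
  if (!length(srcs)) stop("invalid-design: no supplemented source", call. = FALSE)
  dose <- if (dose_scale == "supplemental_nominal") {
    tr$nominal_level
  } else {
    if (anyNA(tr$analyzed_total_mn)) {
      stop("invalid-design: analyzed_total_mn required for supplemental_analyzed",
           call. = FALSE)
    }
    tr$analyzed_total_mn - tr$analyzed_total_mn[tr$source == "none"]
  }
  out <- data.frame(treatment = tr$treatment, stringsAsFactors = FALSE)
  for (s in srcs) out[[s]] <- ifelse(tr$source == s, dose, 0)
  out
}

#' Fit the common-intercept slope-ratio model
#'
#' Ordinary least squares for
#' \deqn{Y = a + b_1 X_1 + b_2 X_2 + \dots}
#' where the \eqn{X_s} are the per-source supplemental dose columns from
#' [encode_doses()] and `a` is the response on the basal (control) diet.
#' `Y` may be replicate-level observations or treatment means; with equal
#' replication the two give identical coefficients.
#'
#' @param Y responses, one per row of `X`.
#' @param X data frame or matrix of per-source dose columns (a `treatment`
#'   column, if present, is dropped).
#' @return an object of class `slope_ratio_fit`: `coefficients` (intercept
#'   `a` then one slope per source), `vcov`, `sigma2`, `df`, `R2`, `p`
#'   (overall model F-test), `sources`.
#' @export
fit_slope_ratio <- function(Y, X) {
  X <- as.data.frame(X)
  X$treatment <- NULL
  if (!nrow(X) || length(Y) != nrow(X)) {
    stop("fit_slope_ratio: Y and X sizes differ", call. = FALSE)
  }
  bad <- vapply(X, function(col) all(col == 0) || stats::var(col) == 0,
                logical(1))
  if (any(bad)) {
    stop("identifiability: constant/zero dose column(s): ",
         paste(names(X)[bad], collapse = ", "), call. = FALSE)
  }
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (qr(M)$rank < ncol(M)) {
    stop("identifiability: design matrix rank-deficient over columns ",
         paste(colnames(M)[-1], collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(Y ~ ., data = data.frame(Y = Y, X, check.names = FALSE))
  # summary.lm warns on an exactly interpolating fit; that is a legitimate
  # use here (noise-free recovery), so that one warning is muffled
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  fstat <- sm$fstatistic
  structure(list(
    coefficients = stats::coef(fit),
    vcov = sm$cov.unscaled * sm$sigma^2,
    sigma2 = sm$sigma^2,
    df = fit$df.residual,
    R2 = sm$r.squared,
    p = if (!is.null(fstat)) stats::pf(fstat[1], fstat[2], fstat[3],
                                       lower.tail = FALSE) else NA_real_,
    sources = names(X),
    lm = fit
  ), class = "slope_ratio_fit")
}

#' @export
print.slope_ratio_fit <- function(x, ...) {
  cat("Slope-ratio model: Y = a + sum_s b_s X_s\n")
  print(signif(x$coefficients, 5))
  cat(sprintf("R2 = %.3f, model p = %.4g, error df = %d\n", x$R2,
              unname(x$p), x$df))
  invisible(x)
}

#' Assemble a slope-ratio fit from given coefficients
#'
#' Wraps externally obtained (e.g. published) slope-ratio coefficients in a
#' `slope_ratio_fit` object so that [rbe()] can be applied to them. Without
#' a covariance matrix the coefficients are treated as known constants and
#' confidence intervals collapse to the point ratio.
#'
#' @param intercept the common intercept `a`.
#' @param slopes named numeric vector of per-source slopes.
#' @param vcov optional covariance matrix of the slopes (source x source).
#' @param df residual degrees of freedom associated with `vcov`.
#' @param R2,p optional fit statistics to carry along.
#' @return a `slope_ratio_fit` object.
#' @export
as_slope_ratio_fit <- function(intercept, slopes, vcov = NULL, df = Inf,
                               R2 = NA_real_, p = NA_real_) {
  stopifnot(is.numeric(slopes), !is.null(names(slopes)))
  srcs <- names(slopes)
  if (is.null(vcov)) {
    vcov <- matrix(0, length(srcs), length(srcs),
                   dimnames = list(srcs, srcs))
  }
  co <- c(`(Intercept)` = intercept, slopes)
  structure(list(coefficients = co, vcov = vcov, sigma2 = NA_real_, df = df,
                 R2 = R2, p = p, sources = srcs, lm = NULL),
            class = "slope_ratio_fit")
}

#' Relative bio-efficacy from a slope-ratio fit
#'
#' RBE of each source versus the reference source: 100 x b_source / b_ref,
#' reported at full precision and rounded to integer percent. Confidence
#' intervals for the slope ratio are given both by Fieller's theorem (exact
#' for a ratio of jointly normal estimates; bounds are `NA` when the
#' reference slope is not significantly nonzero and the interval is
#' unbounded) and by the delta method.
#'
#' @param fit a [fit_slope_ratio()] object.
#' @param reference source name whose slope is the denominator (its RBE is
#'   100% by definition).
#' @param level confidence level.
#' @param tol minimum |reference slope| (relative to its SE) below which the
#'   ratio is undefined.
#' @return an object of class `rbe_result`: data frame `table` with columns
#'   `source`, `slope`, `rbe` (full precision, %), `rbe_rounded`,
#'   `fieller_lo/hi`, `delta_lo/hi`, plus `reference` and `level`.
#' @export
rbe <- function(fit, reference = "organic", level = 0.95, tol = 1e-12) {
  stopifnot(inherits(fit, "slope_ratio_fit"))
  if (!reference %in% fit$sources) {
    stop("rbe: unknown reference source '", reference, "'", call. = FALSE)
  }
  b <- fit$coefficients[fit$sources]
  V <- fit$vcov[fit$sources, fit$sources, drop = FALSE]
  br <- b[[reference]]
  if (abs(br) <= tol) {
    stop("rbe: reference slope is numerically zero; RBE undefined",
         call. = FALSE)
  }
  tq <- stats::qt(1 - (1 - level) / 2, fit$df)
  rows <- lapply(fit$sources, function(s) {
    bi <- b[[s]]
    rho <- bi / br
    vii <- V[s, s]; vrr <- V[reference, reference]; vir <- V[s, reference]
    if (s == reference) {
      return(data.frame(source = s, slope = bi, rbe = 100, rbe_rounded = 100L,
                        fieller_lo = 100, fieller_hi = 100,
                        delta_lo = 100, delta_hi = 100,
                        stringsAsFactors = FALSE))
    }
    # Fieller: roots of (bi - rho*br)^2 = t^2 (vii - 2 rho vir + rho^2 vrr)
    g <- tq^2 * vrr / br^2
    fl <- fh <- NA_real_
    if (g < 1) {
      ctr <- (rho - g * vir / vrr) / (1 - g)
      half <- tq / (abs(br) * (1 - g)) *
        sqrt(vii - 2 * rho * vir + rho^2 * vrr - g * (vii - vir^2 / vrr))
      fl <- 100 * (ctr - half); fh <- 100 * (ctr + half)
    }
    dse <- abs(rho) * sqrt(max(0, vii / bi^2 + vrr / br^2 -
                                 2 * vir / (bi * br)))
    data.frame(source = s, slope = bi, rbe = 100 * rho,
               rbe_rounded = as.integer(round(100 * rho)),
               fieller_lo = fl, fieller_hi = fh,
               delta_lo = 100 * (rho - tq * dse),
               delta_hi = 100 * (rho + tq * dse),
               stringsAsFactors = FALSE)
  })
  structure(list(table = do.call(rbind, rows), reference = reference,
                 level = level), class = "rbe_result")
}

#' @export
print.rbe_result <- function(x, ...) {
  cat(sprintf("Relative bio-efficacy (reference: %s, %g%% CI)\n",
              x$reference, 100 * x$level))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 5))
  print(tab, row.names = FALSE)
  invisible(x)
}
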