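#' One-way treatment ANOVA for a trait
#'
#' Classical fixed-effects one-way analysis of variance with the replicate
#' as the experimental unit, returning least-squares treatment means, the
#' pooled error mean square, SEM = sqrt(MSE/r), the overall F test and a
#' Tukey compact letter display. With unbalanced replication per-treatment
#' SEMs are reported (with a warning) and letters use the Tukey-Kramer
#' critical differences.
#'
#' @param data data frame holding one row per experimental unit.
#' @param trait name of the response column.
#' @param treatment name of the grouping column (default `"treatment"`);
#'   factor level order (or first-appearance order) is preserved.
#' @param alpha significance level for the letter display.
#' @return an object of class `anova_result`: `means` (treatment, n, mean,
#'   letter), `MSE`, `df`, `SEM`, `F`, `p`, `alpha`, `trait`.
#' @export
one_way_anova <- function(data, trait, treatment = "treatment",
                          alpha = 0.05) {
  y <- data[[trait]]
  gvar <- data[[treatment]]
  if (is.null(y)) stop("unknown trait column: ", trait, call. = FALSE)
  if (is.null(gvar)) stop("unknown treatment column: ", treatment, call. = FALSE)
  keep <- is.finite(y) & !is.na(gvar)
  y <- y[keep]
  gvar <- gvar[keep]
  g <- if (is.factor(gvar)) droplevels(gvar) else factor(gvar, levels = unique(gvar))
  k <- nlevels(g)
  n_i <- as.integer(table(g))
  if (k < 2L) stop("need >= 2 treatments", call. = FALSE)
  if (any(n_i < 2L)) stop("need >= 2 replicates per treatment", call. = FALSE)

  fit <- stats::aov(y ~ g)
  # zero-residual layouts (constant data, noise-free simulations) are
  # legitimate here; the F statistic is handled explicitly below
  an <- withCallingHandlers(
    stats::anova(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  mse <- an[["Mean Sq"]][2]
  df <- an[["Df"]][2]
  Fv <- an[["F value"]][1]
  pv <- an[["Pr(>F)"]][1]
  if (stats::var(y) == 0) {  # all observations identical
    Fv <- 0; pv <- 1; mse <- 0
  }
  means <- tapply(y, g, mean)

  balanced <- length(unique(n_i)) == 1L
  if (!balanced) {
    warning("unbalanced replication: reporting per-treatment SEMs and Tukey-Kramer letters",
            call. = FALSE)
  }
  sem <- if (balanced) sqrt(mse / n_i[1]) else sqrt(mse / n_i)

  letters <- tukey_cld(means, MSE = mse, df = df, r = n_i, alpha = alpha)

  structure(list(
    trait = trait,
    means = data.frame(treatment = levels(g), n = n_i,
                       mean = as.numeric(means), letter = letters,
                       stringsAsFactors = FALSE),
    MSE = mse, df = df, SEM = sem, F = Fv, p = pv, alpha = alpha
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA of %s: F = %.4g on %d error df, p = %.4g\n",
              x$trait, x$F, x$df, x$p))
  cat(sprintf("pooled MSE = %.5g, SEM = %s\n", x$MSE,
              paste(signif(x$SEM, 4), collapse = "/")))
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Tukey compact letter display
#'
#' Assigns letters so that any two treatments whose mean difference exceeds
#' the Tukey honestly-significant difference share no letter. With equal
#' replication the critical difference is `q * sqrt(MSE/r)`; with unequal
#' replication the Tukey-Kramer form `q * sqrt(MSE/2 * (1/ri + 1/rj))` is
#' used per pair. Letters are built by the insert-and-absorb algorithm;
#' ties and letter order follow the input treatment order.
#'
#' @param means named (or plain) numeric vector of treatment means.
#' @param MSE pooled error mean square.
#' @param df error degrees of freedom (> 0).
#' @param r replicates per treatment (scalar or one per mean).
#' @param alpha significance level.
#' @return character vector of letter strings, parallel to `means`.
#' @export
tukey_cld <- function(means, MSE, df, r, alpha = 0.05) {
  k <- length(means)
  if (df <= 0) stop("tukey_cld: error df must be > 0", call. = FALSE)
  r <- rep_len(r, k)
  q <- stats::qtukey(1 - alpha, k, df)
  crit <- function(i, j) q * sqrt(MSE / 2 * (1 / r[i] + 1 / r[j]))
  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > crit(i, j)
    }
  }
  # insert-and-absorb: columns are letter groups (TRUE = member)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      for (ci in seq_along(cols)) {
        col <- cols[[ci]]
        if (col[i] && col[j]) {
          c1 <- col; c1[i] <- FALSE
          c2 <- col; c2[j] <- FALSE
          cols[[ci]] <- c1
          cols[[length(cols) + 1L]] <- c2
        }
      }
      # absorb columns that are subsets of another
      drop <- rep(FALSE, length(cols))
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a != b && !drop[a] && !drop[b] &&
              all(!cols[[a]] | cols[[b]]) && any(cols[[b]] & !cols[[a]])) {
            drop[a] <- TRUE
          }
        }
      }
      # also drop exact duplicates
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (a < b && !drop[a] && !drop[b] &&
              identical(cols[[a]], cols[[b]])) drop[b] <- TRUE
        }
      }
      cols <- cols[!drop]
    }
  }
  # order letter groups by the first treatment they contain
  ord <- order(vapply(cols, function(cc) which(cc)[1], numeric(1)))
  cols <- cols[ord]
  out <- character(k)
  for (ci in seq_along(cols)) {
    lab <- letters[ci]
    for (i in which(cols[[ci]])) out[i] <- paste0(out[i], lab)
  }
  out
}

#' Orthogonal polynomial dose contrasts
#'
#' Linear and quadratic single-df contrasts of treatment means against the
#' actual (possibly unequally spaced) dose values, built by QR
#' orthogonalisation of (x, x^2) against the constant vector
#' ([stats::poly()]), and tested against the pooled error mean square of the
#' full ANOVA. With equally spaced doses the linear coefficients reduce to
#' the classical tabulated values (e.g. proportional to -3, -1, 1, 3 for
#' four levels).
#'
#' @param means treatment means of one source arm including the control,
#'   ordered as `doses`.
#' @param doses dose values (mg/kg), same length as `means`, >= 3 distinct
#'   for the quadratic contrast (otherwise it is omitted with a warning).
#' @param MSE pooled error mean square from the full ANOVA.
#' @param df error degrees of freedom.
#' @param r replicates per treatment mean.
#' @return data frame with one row per contrast (`linear`, `quadratic`):
#'   `estimate`, `se`, `t`, `p`, and the contrast coefficients as a matrix
#'   attribute `"coefficients"`.
#' @export
poly_dose_contrasts <- function(means, doses, MSE, df, r) {
  stopifnot(length(means) == length(doses))
  if (length(unique(doses)) < length(doses)) {
    stop("poly_dose_contrasts: duplicated dose levels", call. = FALSE)
  }
  degree <- if (length(unique(doses)) >= 3L) 2L else 1L
  if (degree == 1L) {
    warning("fewer than 3 dose levels: quadratic contrast omitted",
            call. = FALSE)
  }
  cf <- stats::poly(doses, degree = degree)  # orthonormal, zero-sum columns
  labs <- c("linear", "quadratic")[seq_len(degree)]
  r <- rep_len(r, length(means))
  rows <- lapply(seq_len(degree), function(d) {
    cc <- cf[, d]
    est <- sum(cc * means)
    se <- sqrt(MSE * sum(cc^2 / r))
    tv <- est / se
    data.frame(contrast = labs[d], estimate = est, se = se, t = tv,
               p = 2 * stats::pt(-abs(tv), df), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "coefficients") <- matrix(cf[, seq_len(degree)],
                                      ncol = degree,
                                      dimnames = list(NULL, labs))
  out
}

#' Per-source dose-response ANOVA summary
#'
#' Runs the one-way treatment ANOVA for a trait and, for each nutrient
#' source arm (control + its dose levels, the control dose shared across
#' arms), the linear and quadratic orthogonal polynomial contrasts against
#' the pooled error term -- the layout of a dose-response report table.
#'
#' @param traits trait table from [compute_traits()] (or any data frame with
#'   a `treatment` column matching the design).
#' @param design a [trial_design()].
#' @param trait response column name.
#' @param period restrict to this period (default `"overall"` if present).
#' @param dose_scale dose values used for the contrasts.
#' @param alpha letter-display significance level.
#' @return list with `anova` (an `anova_result`) and `contrasts` (data frame
#'   source x contrast with p-values).
#' @export
dose_response_anova <- function(traits, design, trait, period = NULL,
                                dose_scale = c("analyzed", "nominal"),
                                alpha = 0.05) {
  dose_scale <- match.arg(dose_scale)
  stopifnot(inherits(design, "trial_design"))
  d <- traits
  if (!is.null(d$period)) {
    period <- period %||% if ("overall" %in% d$period) "overall"
                          else unique(d$period)[1]
    d <- d[d$period == period, , drop = FALSE]
  }
  d$treatment <- factor(d$treatment, levels = design$treatments$treatment)
  res <- one_way_anova(d, trait, alpha = alpha)

  doses <- design_doses(design, dose_scale)
  tr <- design$treatments
  ctrl <- which(tr$source == "none")
  srcs <- setdiff(unique(tr$source), "none")
  r <- res$means$n
  ctr <- lapply(srcs, function(s) {
    idx <- c(ctrl, which(tr$source == s))
    idx <- idx[order(doses[idx])]
    pc <- poly_dose_contrasts(res$means$mean[idx], doses[idx],
                              MSE = res$MSE, df = res$df, r = r[idx])
    data.frame(source = s, contrast = pc$contrast, estimate = pc$estimate,
               p = pc$p, stringsAsFactors = FALSE)
  })
  list(anova = res, contrasts = do.call(rbind, ctr), period = period)
}
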