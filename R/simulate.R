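#' Generative truth for one simulated trait
#'
#' Couples a dose-response model with replicate-level Gaussian noise. The
#' model may be a single number (dose-independent trait), a [bl_params()]
#' broken-line model shared by every source, or a named list of
#' [bl_params()] models keyed by source (`"oxide"`, `"sulphate"`,
#' `"organic"`, optionally `"none"` for the control; without a `"none"`
#' entry the control expectation is the average of the source models
#' evaluated at the control dose).
#'
#' @param model numeric scalar, [bl_params()], or named list of
#'   [bl_params()] by source.
#' @param noise_sd replicate-level standard deviation, trait units (>= 0).
#' @return an object of class `trait_truth`.
#' @export
trait_truth <- function(model, noise_sd = 0) {
  if (noise_sd < 0) stop("invalid-truth: noise_sd must be >= 0", call. = FALSE)
  ok <- is.numeric(model) && length(model) == 1L ||
    inherits(model, "bl_params") ||
    (is.list(model) && length(model) > 0 &&
       all(vapply(model, inherits, logical(1), "bl_params")) &&
       !is.null(names(model)))
  if (!ok) {
    stop("invalid-truth: model must be a scalar, bl_params, or named list of bl_params",
         call. = FALSE)
  }
  structure(list(model = model, noise_sd = noise_sd), class = "trait_truth")
}

#' Evaluate a trait truth at given doses
#'
#' @param truth a [trait_truth()].
#' @param dose dietary concentration(s), mg/kg.
#' @param source source name(s), recycled against `dose`; used when the
#'   truth carries per-source models.
#' @return expected trait value(s), noise-free.
#' @export
eval_truth <- function(truth, dose, source = "none") {
  stopifnot(inherits(truth, "trait_truth"))
  m <- truth$model
  if (is.numeric(m)) return(rep(m, length(dose)))
  if (inherits(m, "bl_params")) return(bl_predict(m, dose))
  source <- rep_len(as.character(source), length(dose))
  vapply(seq_along(dose), function(i) {
    s <- source[i]
    if (!is.null(m[[s]])) {
      bl_predict(m[[s]], dose[i])
    } else {
      mean(vapply(m, function(mm) bl_predict(mm, dose[i]), numeric(1)))
    }
  }, numeric(1))
}

#' Simulate replicate-level laying records
#'
#' Generates internally consistent replicate-by-period records (hen-days,
#' egg counts and mass, feed offered/residual, mortality) whose derived
#' traits follow the supplied generative truth evaluated at each treatment's
#' total dietary Mn concentration, plus independent replicate-level Gaussian
#' noise. Noise is applied at the replicate level because the replicate is
#' the experimental unit of the emulated trial design.
#'
#' Egg production draws falling outside \[0, 100\]% are clipped, with a
#' warning reporting the clip count. With `round_eggs = TRUE` egg counts are
#' integers, the fractional remainder being carried across the periods of
#' each replicate so no systematic bias accumulates; the default keeps exact
#' expected counts so that noise-free records reproduce the generative trait
#' values to machine precision.
#'
#' @param design a [trial_design()].
#' @param truth named list of [trait_truth()] objects; `ep` (hen-day egg
#'   production, %) is required, `egg_weight` (g) and `fi` (g/bird/day)
#'   optional (defaults 62.8 g and 115.2 g/b/d, noise-free).
#' @param seed integer seed; identical design + truth + seed give identical
#'   tables.
#' @param round_eggs integer egg counts with carried remainder (see above).
#' @param mortality_rate per-bird probability of death within a period;
#'   deaths are assumed at mid-period when computing realised hen-days.
#' @param residual_frac residual feed as a fraction of feed offered.
#' @param dose_scale `"analyzed"` or `"nominal"` dose passed to the truth.
#' @return data frame with columns `treatment`, `replicate`, `period`,
#'   `hen_days`, `eggs_laid`, `total_egg_weight_g`, `feed_offered_g`,
#'   `feed_residual_g`, `mortality`.
#' @export
simulate_replicates <- function(design, truth, seed = 20230315,
                                round_eggs = FALSE, mortality_rate = 0,
                                residual_frac = 0.02,
                                dose_scale = c("analyzed", "nominal")) {
  stopifnot(inherits(design, "trial_design"))
  dose_scale <- match.arg(dose_scale)
  if (is.null(truth$ep)) stop("invalid-truth: truth$ep is required", call. = FALSE)
  truth$egg_weight <- truth$egg_weight %||% trait_truth(62.8)
  truth$fi <- truth$fi %||% trait_truth(115.2)
  for (t in truth) stopifnot(inherits(t, "trait_truth"))
  if (residual_frac < 0 || residual_frac >= 1) {
    stop("invalid-parameter: residual_frac must be in [0, 1)", call. = FALSE)
  }

  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- design$treatments
  doses <- design_doses(design, dose_scale)
  g <- expand.grid(period = seq_len(design$n_periods),
                   replicate = seq_len(design$n_replicates),
                   treatment = tr$treatment)
  g <- g[order(match(g$treatment, tr$treatment), g$replicate, g$period), ,
         drop = FALSE]
  n <- nrow(g)
  ti <- match(g$treatment, tr$treatment)
  g_dose <- doses[ti]
  g_src <- tr$source[ti]

  birds <- design$birds_per_replicate
  days <- design$period_days
  deaths <- if (mortality_rate > 0) stats::rbinom(n, birds, mortality_rate)
            else integer(n)
  hen_days <- (birds - deaths) * days + deaths * (days / 2)

  ep <- eval_truth(truth$ep, g_dose, g_src) +
    stats::rnorm(n, 0, truth$ep$noise_sd)
  n_clip <- sum(ep < 0 | ep > 100)
  if (n_clip > 0) {
    warning(sprintf("simulate_replicates: %d EP draw(s) clipped to [0, 100]",
                    n_clip), call. = FALSE)
    ep <- pmin(pmax(ep, 0), 100)
  }

  eggs <- hen_days * ep / 100
  if (round_eggs) {
    # carry the fractional remainder across each replicate's periods
    for (key in unique(paste(g$treatment, g$replicate))) {
      idx <- which(paste(g$treatment, g$replicate) == key)
      carry <- 0
      for (i in idx) {
        want <- eggs[i] + carry
        got <- round(want)
        carry <- want - got
        eggs[i] <- min(got, floor(hen_days[i]))
      }
    }
  }

  mew <- eval_truth(truth$egg_weight, g_dose, g_src) +
    stats::rnorm(n, 0, truth$egg_weight$noise_sd)
  if (any(mew <= 0)) stop("invalid-parameter: non-positive egg weight drawn",
                          call. = FALSE)
  fi <- eval_truth(truth$fi, g_dose, g_src) +
    stats::rnorm(n, 0, truth$fi$noise_sd)
  fi <- pmax(fi, 0)
  consumed <- fi * hen_days
  offered <- consumed / (1 - residual_frac)

  data.frame(
    treatment = g$treatment,
    replicate = g$replicate,
    period = g$period,
    hen_days = hen_days,
    eggs_laid = eggs,
    total_egg_weight_g = eggs * mew,
    feed_offered_g = offered,
    feed_residual_g = offered - consumed,
    mortality = deaths,
    stringsAsFactors = FALSE
  )
}

#' Simulate egg-level quality records
#'
#' Draws `n_eggs` sampled eggs per replicate per period around per-treatment
#' mean egg characteristics with independent Gaussian noise, enforcing the
#' physical invariants (width <= length, yolk + shell < whole egg, all
#' measurements positive) by rejection sampling with a bounded retry count.
#' Zero noise reproduces the treatment means exactly.
#'
#' @param design a [trial_design()].
#' @param egg_means data frame with one row per treatment (recycled from a
#'   single row) and columns `egg_weight_g`, `width_mm`, `length_mm`,
#'   `albumen_height_mm`, `yolk_g`, `shell_g`, `thick_top_um`,
#'   `thick_mid_um`, `thick_bot_um`.
#' @param noise_sd named numeric of per-variable standard deviations
#'   (defaults 0 for unnamed variables).
#' @param seed integer seed.
#' @param n_eggs eggs sampled per replicate per period.
#' @param max_tries rejection-sampling bound per egg before erroring.
#' @return data frame of egg records keyed by
#'   (treatment, replicate, period, egg_id).
#' @export
simulate_eggs <- function(design, egg_means = mn_reference_egg_means(),
                          noise_sd = NULL, seed = 20230315, n_eggs = 6,
                          max_tries = 1000) {
  stopifnot(inherits(design, "trial_design"))
  vars <- c("egg_weight_g", "width_mm", "length_mm", "albumen_height_mm",
            "yolk_g", "shell_g", "thick_top_um", "thick_mid_um",
            "thick_bot_um")
  em <- as.data.frame(egg_means)
  miss <- setdiff(vars, names(em))
  if (length(miss)) {
    stop("invalid-parameter: egg_means lacks ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tr <- design$treatments
  if (nrow(em) == 1L) em <- em[rep(1L, nrow(tr)), , drop = FALSE]
  if (nrow(em) != nrow(tr)) {
    stop("invalid-parameter: egg_means must have 1 row or one per treatment",
         call. = FALSE)
  }
  bad <- em$width_mm > em$length_mm | em$yolk_g + em$shell_g >= em$egg_weight_g |
    apply(em[vars] <= 0, 1, any)
  if (any(bad)) {
    stop("invalid-parameter: inconsistent egg means in row(s) ",
         paste(which(bad), collapse = ","), call. = FALSE)
  }
  sd <- stats::setNames(numeric(length(vars)), vars)
  if (!is.null(noise_sd)) sd[names(noise_sd)] <- noise_sd

  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- vector("list",
                 nrow(tr) * design$n_replicates * design$n_periods * n_eggs)
  k <- 0L
  for (i in seq_len(nrow(tr))) {
    mu <- as.numeric(em[i, vars])
    for (rep_ in seq_len(design$n_replicates)) {
      for (per in seq_len(design$n_periods)) {
        for (e in seq_len(n_eggs)) {
          for (try in seq_len(max_tries)) {
            x <- mu + stats::rnorm(length(vars), 0, sd)
            ok <- all(x > 0) && x[2] <= x[3] && x[5] + x[6] < x[1]
            if (ok) break
            if (try == max_tries) {
              stop("invalid-parameter: rejection-sampling limit reached; egg means/noise incompatible with invariants",
                   call. = FALSE)
            }
          }
          k <- k + 1L
          rows[[k]] <- c(i, rep_, per, e, x)
        }
      }
    }
  }
  m <- do.call(rbind, rows)
  out <- data.frame(treatment = tr$treatment[m[, 1]], replicate = m[, 2],
                    period = m[, 3], egg_id = m[, 4],
                    stringsAsFactors = FALSE)
  out[vars] <- m[, 5:13]
  out
}

#' Reference generative truth for the built-in manganese trial
#'
#' Per-source broken-line truths for hen-day egg production taken from the
#' fitted models reported for the emulated trial (oxide: linear broken-line,
#' plateau 75.77%, rate -0.07, break 82 mg/kg; sulphate: quadratic
#' broken-line, plateau 78.17%, rate -0.009, break 40; organic: quadratic,
#' plateau 77.84%, rate -0.014, break 33), with replicate-level noise sd
#' calibrated as SEM x sqrt(6) from the reported treatment SEMs (EP 1.67 ->
#' 4.1; egg weight 0.57 -> 1.4; feed intake 1.57 -> 3.8). Egg weight and
#' feed intake are dose-independent.
#'
#' @return named list of [trait_truth()] objects (`ep`, `egg_weight`, `fi`).
#' @export
mn_reference_truth <- function() {
  list(
    ep = trait_truth(list(
      oxide = bl_params("LBL", L = 75.77, U = -0.07, R = 82),
      sulphate = bl_params("QBL", L = 78.17, U = -0.009, R = 40),
      organic = bl_params("QBL", L = 77.84, U = -0.014, R = 33)
    ), noise_sd = 4.1),
    egg_weight = trait_truth(62.8, noise_sd = 1.4),
    fi = trait_truth(115.2, noise_sd = 3.8)
  )
}

#' Reference egg-quality means for the built-in manganese trial
#'
#' A single row of realistic mean egg characteristics for an aged Hy-Line
#' W-36 flock, consistent with the reported overall quality traits
#' (shape index ~76.5%, Haugh unit ~91, relative shell weight ~9.3 g/100 g,
#' shell thickness ~383 um).
#'
#' @return one-row data frame in the [simulate_eggs()] schema.
#' @export
mn_reference_egg_means <- function() {
  data.frame(egg_weight_g = 63.0, width_mm = 44.0, length_mm = 57.5,
             albumen_height_mm = 8.4, yolk_g = 17.0, shell_g = 5.9,
             thick_top_um = 383, thick_mid_um = 383, thick_bot_um = 383)
}

#' Default egg-quality noise for [simulate_eggs()]
#'
#' @return named numeric vector of standard deviations.
#' @export
mn_reference_egg_noise <- function() {
  c(egg_weight_g = 2.0, width_mm = 1.0, length_mm = 1.2,
    albumen_height_mm = 0.8, yolk_g = 1.0, shell_g = 0.3,
    thick_top_um = 12, thick_mid_um = 12, thick_bot_um = 12)
}

#' Write a simulated trial to disk
#'
#' Writes `design.json`, `replicates.csv` and (when given) `eggs.csv` in
#' UTF-8 with header rows and "." decimal separators.
#'
#' @param dir output directory (created if needed).
#' @param design a [trial_design()].
#' @param replicates table from [simulate_replicates()].
#' @param eggs optional table from [simulate_eggs()].
#' @param seed seed recorded in `design.json`.
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(dir, design, replicates, eggs = NULL,
                             seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  dj <- file.path(dir, "design.json")
  jsonlite::write_json(
    list(basal_mn = design$basal_mn,
         n_replicates = design$n_replicates,
         birds_per_replicate = design$birds_per_replicate,
         n_periods = design$n_periods,
         period_days = design$period_days,
         seed = seed,
         treatments = design$treatments),
    dj, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  paths <- c(paths, dj)
  rp <- file.path(dir, "replicates.csv")
  utils::write.csv(replicates, rp, row.names = FALSE, fileEncoding = "UTF-8")
  paths <- c(paths, rp)
  if (!is.null(eggs)) {
    ep <- file.path(dir, "eggs.csv")
    utils::write.csv(eggs, ep, row.names = FALSE, fileEncoding = "UTF-8")
    paths <- c(paths, ep)
  }
  invisible(paths)
}
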