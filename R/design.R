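#' Construct a trial design
#'
#' Builds and validates the treatment structure of a supplementation trial:
#' one unsupplemented control plus one or more nutrient sources each fed at
#' one or more added levels. Added nutrient per kg diet is computed from the
#' supplement inclusion rate and the nutrient mass fraction of the additive;
#' total dietary concentration is basal plus added (or the analysed
#' concentration where one is supplied).
#'
#' @param treatments data frame with one row per treatment and columns
#'   `source` (character; `"none"` for the control), `supplement_rate`
#'   (mg additive per kg diet), `mn_fraction` (mass fraction of Mn in the
#'   additive, in (0, 1]; `NA` allowed for the control), and optionally
#'   `nominal_added_mn` (the design label for added Mn, mg/kg, checked
#'   against `supplement_rate * mn_fraction`) and `analyzed_total_mn`
#'   (chemically determined total dietary Mn, mg/kg).
#' @param basal_mn basal dietary Mn concentration, mg/kg as-fed.
#' @param n_replicates replicates (cages/pens) per treatment.
#' @param birds_per_replicate hens per replicate.
#' @param n_periods number of recording periods.
#' @param period_days days per period.
#'
#' @return An object of class `trial_design`: the validated treatment table
#'   (with computed `nominal_added_mn` and `nominal_total_mn`) plus the
#'   design constants as attributes-like list fields.
#' @seealso [make_design()] to build one from a configuration list or JSON
#'   file, [mn_reference_design()] for the built-in 10-treatment manganese
#'   design.
#' @export
trial_design <- function(treatments, basal_mn,
                         n_replicates = 6, birds_per_replicate = 12,
                         n_periods = 3, period_days = 28) {
  treatments <- as.data.frame(treatments, stringsAsFactors = FALSE)
  req <- c("source", "supplement_rate", "mn_fraction")
  missing_cols <- setdiff(req, names(treatments))
  if (length(missing_cols)) {
    stop("invalid-design: treatments lack column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (basal_mn < 0) stop("invalid-design: basal_mn must be >= 0", call. = FALSE)
  for (v in c(n_replicates, birds_per_replicate, n_periods, period_days)) {
    if (length(v) != 1L || is.na(v) || v < 1) {
      stop("invalid-design: design counts must be positive integers", call. = FALSE)
    }
  }

  src <- as.character(treatments$source)
  is_ctrl <- src == "none"
  if (sum(is_ctrl) != 1L) {
    stop("invalid-design: exactly one control ('none') treatment is required",
         call. = FALSE)
  }
  rate <- treatments$supplement_rate
  frac <- treatments$mn_fraction
  if (any(rate < 0, na.rm = TRUE)) {
    stop("invalid-design: negative supplement_rate", call. = FALSE)
  }
  if (rate[is_ctrl] != 0) {
    stop("invalid-design: control treatment must have supplement_rate = 0",
         call. = FALSE)
  }
  bad_frac <- !is_ctrl & (is.na(frac) | frac <= 0 | frac > 1)
  if (any(bad_frac)) {
    stop("invalid-design: mn_fraction must lie in (0, 1] for supplemented treatments",
         call. = FALSE)
  }

  added <- ifelse(is_ctrl, 0, rate * frac)
  if (!is.null(treatments$nominal_added_mn)) {
    lab <- treatments$nominal_added_mn
    # rates are printed to the nearest mg/kg, so compare at 0.1 mg/kg
    # resolution with an inclusive half-unit bound
    off <- abs(round(added, 1) - lab)
    if (any(off > 0.5, na.rm = TRUE)) {
      stop("invalid-design: nominal_added_mn inconsistent with rate x fraction (",
           paste(which(off > 0.5), collapse = ","), ")", call. = FALSE)
    }
  } else {
    lab <- ifelse(is_ctrl, 0, round(added))
  }

  if (!is.null(treatments$analyzed_total_mn)) {
    an <- treatments$analyzed_total_mn
    if (any(!is.na(an) & an < basal_mn)) {
      stop("invalid-design: analyzed_total_mn below basal_mn", call. = FALSE)
    }
  } else {
    treatments$analyzed_total_mn <- NA_real_
  }

  out <- data.frame(
    treatment = if (is.null(treatments$treatment)) seq_len(nrow(treatments))
                else treatments$treatment,
    source = src,
    supplement_rate = rate,
    mn_fraction = frac,
    nominal_added_mn = added,
    nominal_level = lab,
    nominal_total_mn = basal_mn + added,
    analyzed_total_mn = treatments$analyzed_total_mn,
    stringsAsFactors = FALSE
  )
  structure(
    list(treatments = out, basal_mn = basal_mn,
         n_replicates = as.integer(n_replicates),
         birds_per_replicate = as.integer(birds_per_replicate),
         n_periods = as.integer(n_periods),
         period_days = as.integer(period_days)),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d treatments, %d replicates x %d birds, %d periods of %d d\n",
              nrow(x$treatments), x$n_replicates, x$birds_per_replicate,
              x$n_periods, x$period_days))
  cat(sprintf("Basal Mn: %.1f mg/kg\n", x$basal_mn))
  print(x$treatments, row.names = FALSE)
  invisible(x)
}

#' Build a trial design from a configuration
#'
#' Accepts either a list (e.g. parsed from `design.json`) or a path to a JSON
#' file with fields `basal_mn`, `n_replicates`, `birds_per_replicate`,
#' `n_periods`, `period_days` and a `treatments` table (or a compact
#' `sources`/`rates`/`fractions` block which is expanded to one control plus
#' every source-by-rate combination).
#'
#' @param config list or path to a JSON file.
#' @return a [trial_design()] object.
#' @export
make_design <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("invalid-design: config must be a list or JSON path",
                             call. = FALSE)
  if (is.null(config$treatments) && !is.null(config$sources)) {
    rows <- list(data.frame(source = "none", supplement_rate = 0,
                            mn_fraction = NA_real_, stringsAsFactors = FALSE))
    for (i in seq_along(config$sources)) {
      s <- config$sources[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        source = s$name,
        supplement_rate = as.numeric(s$rates),
        mn_fraction = as.numeric(s$mn_fraction),
        stringsAsFactors = FALSE)
    }
    config$treatments <- do.call(rbind, rows)
  }
  trial_design(
    treatments = config$treatments,
    basal_mn = config$basal_mn,
    n_replicates = config$n_replicates %||% 6,
    birds_per_replicate = config$birds_per_replicate %||% 12,
    n_periods = config$n_periods %||% 3,
    period_days = config$period_days %||% 28
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dietary dose used as the regression abscissa
#'
#' Total dietary concentration per treatment: the chemically analysed value
#' when available (`scale = "analyzed"`, the default, matching how fitted
#' dose-response models are usually reported) or the nominal basal-plus-added
#' value (`scale = "nominal"`).
#'
#' @param design a [trial_design()].
#' @param scale `"analyzed"` or `"nominal"`.
#' @return numeric vector of doses (mg/kg), one per treatment.
#' @export
design_doses <- function(design, scale = c("analyzed", "nominal")) {
  scale <- match.arg(scale)
  tr <- design$treatments
  if (scale == "analyzed") {
    if (anyNA(tr$analyzed_total_mn)) {
      stop("invalid-design: analyzed_total_mn missing; use scale = 'nominal'",
           call. = FALSE)
    }
    tr$analyzed_total_mn
  } else {
    tr$nominal_total_mn
  }
}

#' The built-in 10-treatment manganese trial design
#'
#' The design of a published 12-week dose-response trial in aged Hy-Line W-36
#' laying hens (87-98 weeks): an unsupplemented control (basal 10.3 mg/kg Mn,
#' analysed 10.4) plus three Mn sources, each at three added levels of
#' nominally 30, 60 and 90 mg/kg Mn -- Mn-oxide (Mn2O3, 69.62% Mn, fed at 43,
#' 86 and 130 mg additive/kg), Mn-sulphate (MnSO4.H2O, 36.4% Mn, at 82, 164
#' and 247 mg/kg) and an organic Mn amino-acid complex (10% Mn, at 300, 600
#' and 900 mg/kg) -- with 6 replicates of 12 hens per treatment over three
#' 28-day periods. Analysed total Mn concentrations of the diets are included.
#'
#' @return a [trial_design()] object.
#' @export
mn_reference_design <- function() {
  treatments <- data.frame(
    source = c("none",
               rep("oxide", 3), rep("sulphate", 3), rep("organic", 3)),
    supplement_rate = c(0, 43, 86, 130, 82, 164, 247, 300, 600, 900),
    mn_fraction = c(NA, rep(0.6962, 3), rep(0.364, 3), rep(0.10, 3)),
    nominal_added_mn = c(0, 30, 60, 90, 30, 60, 90, 30, 60, 90),
    analyzed_total_mn = c(10.4,
                          40.20, 70.75, 100.60,
                          40.25, 70.70, 100.25,
                          40.60, 70.20, 100.70),
    stringsAsFactors = FALSE
  )
  trial_design(treatments, basal_mn = 10.3,
               n_replicates = 6, birds_per_replicate = 12,
               n_periods = 3, period_days = 28)
}
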