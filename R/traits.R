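#' Hen-day egg production
#'
#' Eggs laid per 100 realised bird-days, the standard production measure for
#' layer trials (mortality-adjusted through the bird-day denominator).
#'
#' @param eggs_laid number of eggs laid over the period.
#' @param hen_days realised bird-days over the same period.
#' @return percentage in \[0, 100\].
#' @export
hen_day_ep <- function(eggs_laid, hen_days) {
  if (any(hen_days <= 0)) stop("undefined-trait: hen_days must be > 0", call. = FALSE)
  if (any(eggs_laid < 0)) stop("data-integrity: negative egg count", call. = FALSE)
  if (any(eggs_laid > hen_days)) {
    stop("data-integrity: eggs_laid exceeds hen_days", call. = FALSE)
  }
  100 * eggs_laid / hen_days
}

#' Daily feed intake per bird
#'
#' Feed disappearance (offered minus residual) divided by realised bird-days.
#'
#' @param feed_offered g offered over the period.
#' @param feed_residual g left in feeders at the end of the period.
#' @param hen_days realised bird-days.
#' @return g per bird per day.
#' @export
feed_intake <- function(feed_offered, feed_residual, hen_days) {
  if (any(hen_days <= 0)) stop("undefined-trait: hen_days must be > 0", call. = FALSE)
  if (any(feed_offered < 0 | feed_residual < 0)) {
    stop("data-integrity: negative feed mass", call. = FALSE)
  }
  if (any(feed_residual > feed_offered)) {
    stop("data-integrity: residual feed exceeds feed offered", call. = FALSE)
  }
  (feed_offered - feed_residual) / hen_days
}

#' Feed conversion ratio
#'
#' Total feed intake divided by total egg mass (g feed per g egg; lower is
#' better). Computed on summed totals, never as a mean of per-period ratios.
#'
#' @param total_feed_intake g feed consumed.
#' @param total_egg_mass g egg produced.
#' @return dimensionless ratio.
#' @export
fcr <- function(total_feed_intake, total_egg_mass) {
  if (any(total_egg_mass <= 0)) {
    stop("undefined-trait: total egg mass must be > 0", call. = FALSE)
  }
  total_feed_intake / total_egg_mass
}

#' Egg shape index
#'
#' Maximum width as a percentage of maximum length.
#'
#' @param width mm.
#' @param length mm.
#' @return percentage in (0, 100\].
#' @export
shape_index <- function(width, length) {
  if (any(width <= 0 | length <= 0)) {
    stop("data-integrity: dimensions must be positive", call. = FALSE)
  }
  if (any(width > length)) {
    stop("data-integrity: egg width exceeds length", call. = FALSE)
  }
  100 * width / length
}

#' Haugh unit
#'
#' Albumen-quality index from albumen height corrected for egg weight:
#' \deqn{HU = 100 \log_{10}(h + 7.57 - 1.7\, W^{0.37})}
#' with height `h` in mm and weight `W` in g.
#'
#' @param albumen_height mm.
#' @param egg_weight g.
#' @return Haugh units.
#' @export
haugh_unit <- function(albumen_height, egg_weight) {
  if (any(egg_weight <= 0)) stop("data-integrity: egg weight must be positive",
                                 call. = FALSE)
  arg <- albumen_height + 7.57 - 1.7 * egg_weight^0.37
  if (any(arg <= 0)) {
    stop(sprintf(
      "undefined-trait: non-positive Haugh log argument (min %.4g); albumen height too small for egg weight",
      min(arg)), call. = FALSE)
  }
  100 * log10(arg)
}

#' Relative eggshell weight
#'
#' Shell weight per 100 g whole-egg weight.
#'
#' @param shell_weight g.
#' @param egg_weight g.
#' @return g shell per 100 g egg, in (0, 100).
#' @export
relative_shell_weight <- function(shell_weight, egg_weight) {
  if (any(shell_weight <= 0 | egg_weight <= 0)) {
    stop("data-integrity: weights must be positive", call. = FALSE)
  }
  if (any(shell_weight >= egg_weight)) {
    stop("data-integrity: shell weight must be below egg weight", call. = FALSE)
  }
  100 * shell_weight / egg_weight
}

#' Mean eggshell thickness
#'
#' Arithmetic mean of the thickness measured at three sites (top, middle,
#' bottom).
#'
#' @param top,middle,bottom micrometres.
#' @return micrometres.
#' @export
mean_shell_thickness <- function(top, middle, bottom) {
  if (any(c(top, middle, bottom) <= 0)) {
    stop("data-integrity: thickness must be positive", call. = FALSE)
  }
  (top + middle + bottom) / 3
}

#' Derived trait table from raw trial records
#'
#' Computes per (treatment, replicate, period) performance traits from
#' replicate laying records, merges per-replicate egg-quality means from
#' egg-level records when supplied, and appends an `"overall"` row per
#' replicate aggregating the periods.
#'
#' Performance traits: hen-day egg production (EP, %), mean egg weight (g),
#' egg mass (EM, g/bird/day), feed intake (FI, g/bird/day) and feed
#' conversion ratio (FCR, on totals). Egg-quality traits (when `eggs` is
#' given): shape index, Haugh unit, relative eggshell weight, yolk and
#' albumen weight (albumen by subtraction of yolk plus shell from the whole
#' egg) and mean shell thickness, averaged over the sampled eggs.
#'
#' The `"overall"` aggregate sums counts and masses across periods before
#' recomputing traits, so overall EP/FI/EM are hen-day-weighted means and
#' overall FCR is the ratio of totals; `overall = "simple"` instead averages
#' the per-period trait values.
#'
#' @param replicates data frame with columns `treatment`, `replicate`,
#'   `period`, `hen_days`, `eggs_laid`, `total_egg_weight_g`,
#'   `feed_offered_g`, `feed_residual_g` (and optionally `mortality`).
#' @param eggs optional data frame of egg records (see [simulate_eggs()] for
#'   the schema).
#' @param overall `"hen_day"` (weighted, the default) or `"simple"`.
#' @return data frame keyed by (treatment, replicate, period) with the
#'   period levels of `replicates` plus `"overall"`.
#' @export
compute_traits <- function(replicates, eggs = NULL,
                           overall = c("hen_day", "simple")) {
  overall <- match.arg(overall)
  r <- as.data.frame(replicates)
  need <- c("treatment", "replicate", "period", "hen_days", "eggs_laid",
            "total_egg_weight_g", "feed_offered_g", "feed_residual_g")
  miss <- setdiff(need, names(r))
  if (length(miss)) {
    stop("data-integrity: replicate records lack column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }

  per_row <- function(d) {
    ep <- hen_day_ep(d$eggs_laid, d$hen_days)
    mew <- ifelse(d$eggs_laid > 0, d$total_egg_weight_g / d$eggs_laid, NA_real_)
    em <- d$total_egg_weight_g / d$hen_days
    fi <- feed_intake(d$feed_offered_g, d$feed_residual_g, d$hen_days)
    data.frame(treatment = d$treatment, replicate = d$replicate,
               period = if (is.null(d$period)) "overall"
                        else as.character(d$period),
               EP = ep, egg_weight = mew, EM = em, FI = fi,
               FCR = fcr(d$feed_offered_g - d$feed_residual_g,
                         d$total_egg_weight_g),
               stringsAsFactors = FALSE)
  }
  out <- per_row(r)

  # overall rows: aggregate raw totals per replicate, then recompute
  agg_keys <- c("treatment", "replicate")
  if (overall == "hen_day") {
    sums <- stats::aggregate(
      r[c("hen_days", "eggs_laid", "total_egg_weight_g",
          "feed_offered_g", "feed_residual_g")],
      by = r[agg_keys], FUN = sum)
    ov <- per_row(sums)
    ov$period <- "overall"
  } else {
    m <- stats::aggregate(out[c("EP", "egg_weight", "EM", "FI", "FCR")],
                          by = out[agg_keys], FUN = mean)
    ov <- data.frame(m[agg_keys], period = "overall",
                     m[c("EP", "egg_weight", "EM", "FI", "FCR")],
                     stringsAsFactors = FALSE)
  }
  out <- rbind(out, ov[names(out)])

  if (!is.null(eggs)) {
    e <- as.data.frame(eggs)
    eneed <- c("treatment", "replicate", "period", "egg_weight_g", "width_mm",
               "length_mm", "albumen_height_mm", "yolk_g", "shell_g",
               "thick_top_um", "thick_mid_um", "thick_bot_um")
    emiss <- setdiff(eneed, names(e))
    if (length(emiss)) {
      stop("data-integrity: egg records lack column(s) ",
           paste(emiss, collapse = ", "), call. = FALSE)
    }
    e$shape_index <- shape_index(e$width_mm, e$length_mm)
    e$haugh_unit <- haugh_unit(e$albumen_height_mm, e$egg_weight_g)
    e$RESW <- relative_shell_weight(e$shell_g, e$egg_weight_g)
    e$shell_thickness <- mean_shell_thickness(e$thick_top_um, e$thick_mid_um,
                                              e$thick_bot_um)
    e$albumen_g <- e$egg_weight_g - e$yolk_g - e$shell_g
    e$period <- as.character(e$period)
    em <- stats::aggregate(
      e[c("shape_index", "haugh_unit", "RESW", "shell_thickness",
          "yolk_g", "albumen_g")],
      by = e[c("treatment", "replicate", "period")], FUN = mean)
    emo <- stats::aggregate(
      e[c("shape_index", "haugh_unit", "RESW", "shell_thickness",
          "yolk_g", "albumen_g")],
      by = e[c("treatment", "replicate")], FUN = mean)
    emo$period <- "overall"
    em <- rbind(em, emo[names(em)])
    out <- merge(out, em, by = c("treatment", "replicate", "period"),
                 all.x = TRUE, sort = FALSE)
  }
  out <- out[order(out$treatment, out$replicate,
                   match(out$period, c(sort(unique(as.character(r$period))),
                                       "overall"))), ]
  rownames(out) <- NULL
  out
}

#' Round a trait table for reporting
#'
#' Report precision: 2 decimals for traits, 3 for FCR; full precision is kept
#' in the computed table itself.
#'
#' @param traits a table from [compute_traits()].
#' @return the table with numeric columns rounded.
#' @export
round_traits <- function(traits) {
  num <- vapply(traits, is.numeric, logical(1))
  for (nm in names(traits)[num]) {
    traits[[nm]] <- round(traits[[nm]], if (nm == "FCR") 3 else 2)
  }
  traits
}
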