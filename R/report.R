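#' Run the full dose-response analysis pipeline
#'
#' Orchestrates the stages end to end: obtain records (read CSV inputs or
#' simulate them from a generative truth), derive the trait table, run the
#' treatment ANOVA with Tukey letters and per-source dose contrasts for each
#' requested trait, fit both broken-line forms per trait and source with
#' model selection, and estimate slope-ratio relative bio-efficacy. All
#' tables are written as CSV (plus JSON for model fits) under `out_dir`
#' together with a manifest recording the package version, seed and input
#' checksums; re-running with the same configuration and seed reproduces
#' byte-identical outputs.
#'
#' The configuration is a list (or path to a JSON file) with exactly one of:
#' \describe{
#'   \item{`inputs`}{list with paths `design` (design.json),
#'     `replicates` (replicates.csv) and optionally `eggs` (eggs.csv).}
#'   \item{`simulate`}{list with optional `design` (config for
#'     [make_design()]; default the built-in manganese design), logical
#'     `eggs` (default TRUE), optional `noise_sd` (named per-trait noise
#'     overrides) and optional `ep_model` (`form`/`L`/`U`/`R`, one shared
#'     broken-line EP truth replacing the per-source reference models).}
#' }
#' plus optional `traits` (default EP, EM, FCR and, when egg records exist,
#' RESW), `alpha` (default 0.05), `dose_scale` (`"analyzed"`/`"nominal"`,
#' for the regression abscissa), `rbe_dose_scale`
#' (`"supplemental_nominal"`/`"supplemental_analyzed"`), `reference`
#' (default `"organic"`), `forms` (default both `"LBL"` and `"QBL"`), and
#' `seed`.
#'
#' @param config list or path to a JSON configuration.
#' @param out_dir output directory (created if needed).
#' @param seed overrides `config$seed` when given.
#' @return invisibly, a list with the design, trait table, per-trait ANOVA
#'   summaries, broken-line selections, the slope-ratio fit and RBE table,
#'   and the manifest.
#' @export
run_report <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) {
    stop("validation: config must be a list or a JSON path", call. = FALSE)
  }
  has_in <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_in == has_sim) {
    stop("validation: exactly one of 'inputs' or 'simulate' must be present",
         call. = FALSE)
  }
  alpha <- config$alpha %||% 0.05
  if (alpha <= 0 || alpha >= 1) {
    stop("validation: alpha must lie in (0, 1)", call. = FALSE)
  }
  seed <- as.integer(seed %||% config$seed %||% 20230315)
  dose_scale <- config$dose_scale %||% "analyzed"
  rbe_scale <- config$rbe_dose_scale %||% "supplemental_nominal"
  reference <- config$reference %||% "organic"
  forms <- config$forms %||% c("LBL", "QBL")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  checksums <- character(0)
  eggs <- NULL
  if (has_in) {
    for (f in c("design", "replicates")) {
      if (is.null(config$inputs[[f]])) {
        stop("validation: inputs$", f, " is required", call. = FALSE)
      }
      if (!file.exists(config$inputs[[f]])) {
        stop("validation: missing input file ", config$inputs[[f]],
             call. = FALSE)
      }
    }
    design <- make_design(config$inputs$design)
    replicates <- utils::read.csv(config$inputs$replicates)
    if (!is.null(config$inputs$eggs)) {
      if (!file.exists(config$inputs$eggs)) {
        stop("validation: missing input file ", config$inputs$eggs,
             call. = FALSE)
      }
      eggs <- utils::read.csv(config$inputs$eggs)
    }
    checksums <- tools::md5sum(unlist(config$inputs))
  } else {
    design <- if (is.null(config$simulate$design)) mn_reference_design()
              else make_design(config$simulate$design)
    truth <- mn_reference_truth()
    if (!is.null(config$simulate$ep_model)) {
      m <- config$simulate$ep_model
      truth$ep$model <- bl_params(m$form, L = m$L, U = m$U, R = m$R)
    }
    for (nm in names(config$simulate$noise_sd %||% list())) {
      if (!is.null(truth[[nm]])) {
        truth[[nm]]$noise_sd <- config$simulate$noise_sd[[nm]]
      }
    }
    replicates <- simulate_replicates(design, truth, seed = seed)
    if (isTRUE(config$simulate$eggs %||% TRUE)) {
      eggs <- simulate_eggs(design, noise_sd = mn_reference_egg_noise(),
                            seed = seed + 1L)
    }
    write_simulation(file.path(out_dir, "simulated"), design, replicates,
                     eggs, seed = seed)
  }

  egg_traits <- c("shape_index", "haugh_unit", "RESW", "shell_thickness")
  traits_req <- config$traits %||%
    c("EP", "EM", "FCR", if (!is.null(eggs)) "RESW")
  bad_egg <- intersect(traits_req, egg_traits)
  if (is.null(eggs) && length(bad_egg)) {
    stop("validation: trait(s) ", paste(bad_egg, collapse = ", "),
         " require egg records but none were provided", call. = FALSE)
  }

  trait_tab <- compute_traits(replicates, eggs)
  utils::write.csv(round_traits(trait_tab), file.path(out_dir, "traits.csv"),
                   row.names = FALSE)

  # ANOVA + dose contrasts per trait (overall period)
  anovas <- list()
  for (tn in traits_req) {
    dr <- dose_response_anova(trait_tab, design, tn, dose_scale = dose_scale,
                              alpha = alpha)
    anovas[[tn]] <- dr
    tab <- dr$anova$means
    foot <- data.frame(
      treatment = c("SEM", "F", "p",
                    paste0(dr$contrasts$source, "_",
                           substr(dr$contrasts$contrast, 1, 1), "_p")),
      n = NA, mean = c(mean(dr$anova$SEM), dr$anova$F, dr$anova$p,
                       dr$contrasts$p),
      letter = "", stringsAsFactors = FALSE)
    utils::write.csv(rbind(tab, foot),
                     file.path(out_dir, paste0("anova_", tn, ".csv")),
                     row.names = FALSE)
  }

  # broken-line requirement per performance trait x source
  perf <- intersect(traits_req, c("EP", "EM", "FCR"))
  doses <- design_doses(design, dose_scale)
  tr <- design$treatments
  overall <- trait_tab[trait_tab$period == "overall", ]
  fits <- list()
  for (tn in perf) {
    for (s in setdiff(unique(tr$source), "none")) {
      idx <- tr$source %in% c("none", s)
      rows <- overall[overall$treatment %in% tr$treatment[idx], ]
      X <- doses[match(rows$treatment, tr$treatment)]
      cand <- lapply(forms, function(fm) bl_fit(X, rows[[tn]], form = fm))
      sel <- select_model(cand)
      fits[[paste(tn, s, sep = "_")]] <- sel
      best <- sel$best
      jsonlite::write_json(
        list(trait = tn, source = s, form = best$params$form,
             L = best$params$L, U = best$params$U, R = best$params$R,
             se = as.list(best$se),
             criteria = sel$table,
             flags = best$flags),
        file.path(out_dir, paste0("fit_", tn, "_", s, ".json")),
        auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    }
  }

  # slope-ratio RBE on overall replicate-level data
  enc <- encode_doses(design, rbe_scale)
  rbe_tabs <- list()
  for (tn in perf) {
    Xrep <- enc[match(overall$treatment, enc$treatment), -1, drop = FALSE]
    sr <- fit_slope_ratio(overall[[tn]], Xrep)
    rb <- rbe(sr, reference = reference)
    rbe_tabs[[tn]] <- cbind(trait = tn, rb$table)
  }
  rbe_tab <- do.call(rbind, rbe_tabs)
  utils::write.csv(rbe_tab, file.path(out_dir, "rbe.csv"), row.names = FALSE)

  manifest <- list(package = "layreq",
                   version = as.character(utils::packageVersion("layreq")),
                   seed = seed, alpha = alpha, dose_scale = dose_scale,
                   rbe_dose_scale = rbe_scale, reference = reference,
                   traits = traits_req,
                   input_md5 = as.list(checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(design = design, traits = trait_tab, anova = anovas,
                 broken_line = fits, rbe = rbe_tab, manifest = manifest))
}
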