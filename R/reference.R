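#' Published slope-ratio coefficients for the reference manganese trial
#'
#' The reported common-intercept slope-ratio regression of each response on
#' the nominal supplemental Mn levels (0/30/60/90 mg/kg) of the emulated
#' trial: intercept (basal-diet response), per-source slope coefficients,
#' model p-value, R-squared, and the relative bio-efficacy percentages as
#' printed in the source report (organic Mn is the reference, 100%).
#'
#' These printed coefficients serve as worked-example inputs: applying
#' [rbe()] to them reproduces the published RBE percentages by direct
#' arithmetic. (One printed cell -- sulphate FCR, 99% -- is internally
#' inconsistent with its own printed slopes, which are equal and therefore
#' give 100%.)
#'
#' @return data frame with one row per trait (`EP`, `EM`, `FCR`, `RESW`):
#'   `intercept`, `b_oxide`, `b_sulphate`, `b_organic`, `p`, `R2`,
#'   `rbe_oxide`, `rbe_sulphate`, `rbe_organic`.
#' @export
mn_reference_slopes <- function() {
  data.frame(
    trait = c("EP", "EM", "FCR", "RESW"),
    intercept = c(72.52, 46.18, 2.520, 9.09),
    b_oxide = c(0.0353, 0.0122, -0.0009, 0.0023),
    b_sulphate = c(0.0684, 0.0380, -0.0025, 0.0047),
    b_organic = c(0.0786, 0.0406, -0.0025, 0.0062),
    p = c(0.001, 0.003, 0.001, 0.010),
    R2 = c(0.26, 0.21, 0.26, 0.20),
    rbe_oxide = c(45L, 30L, 36L, 37L),
    rbe_sulphate = c(87L, 94L, 99L, 76L),
    rbe_organic = c(100L, 100L, 100L, 100L),
    stringsAsFactors = FALSE
  )
}

#' Published broken-line models for the reference manganese trial
#'
#' The fitted broken-line models reported for the emulated trial's egg
#' performance traits as functions of analysed dietary Mn concentration:
#' form (LBL = linear broken-line, QBL = quadratic), plateau `L`, signed
#' rate constant `U`, break point `R` with its reported standard error,
#' model p-value and R-squared. The organic egg-mass plateau is printed as
#' 90.13 in the source, inconsistent with the trait's scale (~49 g/b/d);
#' it is carried verbatim here but flagged (`suspect`).
#'
#' @return data frame, one row per trait x source.
#' @seealso [bl_params()], [mn_reference_truth()]
#' @export
mn_reference_models <- function() {
  data.frame(
    trait = rep(c("EP", "EM", "FCR"), each = 3),
    source = rep(c("oxide", "sulphate", "organic"), 3),
    form = c("LBL", "QBL", "QBL",
             "LBL", "QBL", "QBL",
             "LBL", "QBL", "QBL"),
    L = c(75.77, 78.17, 77.84,
          47.51, 49.21, 90.13,
          2.437, 2.36, 2.33),
    U = c(-0.07, -0.009, -0.014,
          -0.029, -0.005, -0.006,
          0.002, -0.0003, -0.0003),
    R = c(82, 40, 33,
          92, 39, 36,
          89, 38, 39),
    se_R = c(18.5, 7.5, NA,
             15.3, 8.5, NA,
             15.5, 11.6, 10.5),
    p = c(0.015, 0.001, 0.001,
          0.023, 0.002, 0.002,
          0.035, 0.001, 0.001),
    R2 = c(0.23, 0.57, NA,
           0.23, 0.43, NA,
           0.33, 0.45, 0.54),
    suspect = c(FALSE, FALSE, FALSE,
                FALSE, FALSE, TRUE,
                FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Look up one published broken-line model as parameters
#'
#' @param trait `"EP"`, `"EM"` or `"FCR"`.
#' @param source `"oxide"`, `"sulphate"` or `"organic"`.
#' @return a [bl_params()] object.
#' @export
mn_reference_model <- function(trait, source) {
  m <- mn_reference_models()
  row <- m[m$trait == trait & m$source == source, ]
  if (nrow(row) != 1L) {
    stop("no published model for ", trait, " / ", source, call. = FALSE)
  }
  bl_params(row$form, L = row$L, U = row$U, R = row$R)
}
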