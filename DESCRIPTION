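Package: layreq
Title: Nutrient Requirement and Relative Bio-Efficacy Estimation for Layer Dose-Response Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing dose-response trials of trace-mineral
    supplementation in laying hens: computation of performance and egg-quality
    traits (hen-day egg production, egg mass, feed conversion ratio, shape
    index, Haugh unit, relative eggshell weight) from replicate-level laying
    records; one-way treatment ANOVA with Tukey compact letter displays and
    orthogonal polynomial dose contrasts at arbitrary dose spacing; linear and
    quadratic broken-line (plateau) regression with profiled break-point
    estimation, fit-quality criteria and AIC-based model selection for nutrient
    requirement estimation; and slope-ratio multiple regression with Fieller
    confidence intervals for the relative bio-efficacy of nutrient sources.
    Includes a seeded synthetic-trial generator emulating a 10-treatment
    manganese trial (control plus three sources at three added levels) so that
    every stage of the pipeline is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    multcomp
Config/testthat/edition: 3
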