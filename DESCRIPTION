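Package: rmragree
Title: Agreement Between Resting Metabolic Rate Prediction Equations and
    Indirect Calorimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for method-comparison analysis of resting metabolic rate
    (RMR) prediction equations against indirect-calorimetry measurements.
    Implements a configurable library of classical prediction equations
    (Harris-Benedict and revisions, Mifflin, Owen, Schofield, FAO-WHO-UNU),
    per-equation agreement summaries (mean bias with confidence interval,
    absolute bias, percentage accuracy, within-10-percent counts), Box-Cox
    normalised regression of individual absolute bias on gender, BMI class
    and age group with backward elimination, chi-square cross-tabulations
    with standardized residual flagging, and log-linear (power-law) fitting
    of per-kilogram RMR against WHO BMI-class codes to derive BMI-class RMR
    equations. A synthetic-cohort generator reproduces the anthropometric
    structure the analysis assumes so the full pipeline runs without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    MASS,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
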