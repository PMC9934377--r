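Package: ehrisk
Title: Log-Odds-Ratio Risk Scoring and Prospective Validation for Coded EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds Naive-Bayes-style clinical risk models from longitudinal
    coded electronic health record (EHR) data. Each coded feature (diagnosis,
    medication, lab flag, demographic category) receives a partial risk score
    equal to the log odds ratio contrasting its prevalence in cases versus
    controls; a patient's risk score is the sum of the scores of all distinct
    features ever coded. The package covers the full pipeline: a synthetic
    longitudinal EHR cohort generator with planted effect sizes, case
    definition by code prefix, inclusion and exclusion filters, pre-event
    censoring, leakage-free vocabulary construction, threshold calibration at
    benchmark specificities, simulated-prospective validation with cumulative
    risk trajectories, ROC/AUC, lead-time measurement, and a three-arm
    comparison of subpopulation-trained versus general-population-trained
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
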