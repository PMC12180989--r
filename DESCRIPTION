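Package: rxguard
Title: Distance-Based Detection of Atypical Radiation Therapy Prescriptions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Data-driven screening of radiation therapy (RT) prescriptions for
    use alongside physician peer review. A new prescription is compared against
    a site- and technique-specific historical database using two dissimilarity
    statistics: a Euclidean prescription distance over (dose per fraction,
    number of fractions) and a Gower distance over the mixed categorical and
    numeric clinical feature set. Records exceeding calibrated thresholds are
    flagged as prescription or feature anomalies with a per-record explanation.
    The package includes the feature-engineering pipeline (QA-record removal,
    ICD-10 site selection, most-often imputation, diagnostic-code frequency
    weighting, rare-regimen upweighting), conditional-frequency anomaly
    simulation, F1-optimised grid-search calibration with repeated-run
    averaging, chi-squared agreement validation, incremental-learning schemes
    for secular drift (linear time scaling, sliding windows), and a seeded
    synthetic cohort generator so the whole pipeline runs without clinical
    data exports.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
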