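Package: sasscreen
Title: Sleep Apnea Screening Scores and Diagnostic Performance Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the simplified SAS score for obstructive sleep apnea
    screening from body-mass index, neck circumference, systolic blood
    pressure and Epworth sleepiness score, together with the STOP-Bang and
    NoSAS comparator questionnaires. Provides a diagnostic-performance
    engine (confusion matrices, sensitivity, specificity, predictive
    values, ROC/AUC with DeLong and bootstrap confidence intervals, and
    score cut-off sweeps with sensitivity-specificity crossover detection)
    against an apnea-hypopnea-index reference standard, cohort file input
    and output with column mapping and validation, and a seeded synthetic
    cohort generator with a latent severity factor for end-to-end testing
    and prevalence calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
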