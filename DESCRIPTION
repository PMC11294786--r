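Package: nightsigns
Title: Nocturnal Vital-Sign Monitoring Analysis for Remote COPD Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-night nocturnal vital-sign
    recordings (heartbeat intervals and per-minute respiratory rate) for
    remote screening of chronic obstructive pulmonary disease. Provides a
    synthetic cohort generator with controllable group phenotypes, nightly
    heart-rate-variability spectral features from a Lomb-Scargle periodogram
    of the irregularly sampled tachogram, respiration features, night-level
    quality-control exclusions, multi-day trimmed-mean feature aggregation,
    logistic-regression classification with ROC/AUC evaluation (DeLong
    intervals, Youden-index cutoffs), and diagnostic-accuracy sample-size
    estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
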