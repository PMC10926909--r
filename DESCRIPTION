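Package: actikids
Title: Wrist Accelerometry Physical Activity Analysis for Child Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processes raw wrist-worn triaxial accelerometer recordings of
    children into calibrated 5-second ENMO epochs (auto-calibration, clipping
    detection, Euclidean-norm-minus-one with truncation, z-angle), detects
    non-wear time including a strict sustained-inactivity rule, classifies
    calendar days (school days with and without physical education class,
    weekend, holiday), applies day and school-time validity rules, imputes
    residual non-wear by day-type clock-interval averages, and aggregates
    weekly weighted intensity summaries (sedentary, light, moderate, vigorous).
    Derives sex-specific moderate-to-vigorous and vigorous activity
    recommendation thresholds associated with central obesity via ROC curves
    and the Youden index, and evaluates guideline compliance with the
    associated categorical statistics (phi, Cramer's V, chi-square, McNemar,
    rank tests, conditional logistic odds ratios). A synthetic cohort
    generator with a calibrated activity-obesity link makes the full pipeline
    testable without access to individual accelerometer data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'roc.R'
    'assoc.R'
    'utils.R'
    'cutpoints.R'
    'wear.R'
    'day-typing.R'
    'summaries.R'
    'synth-epochs.R'
    'synth-cohort.R'
    'pipeline.R'
    'signal.R'
    'synth-raw.R'
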