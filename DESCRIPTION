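Package: ppgbp
Title: Blood Pressure Estimation from PPG Pulse Morphology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration-based estimation of systolic and diastolic blood
    pressure from photoplethysmogram (PPG) waveform morphology. Implements
    quality-gated ensemble-average pulse construction, pulse wave analysis
    of the PPG and its first three derivatives (velocity, acceleration and
    jerk plethysmograms), calibration-pair dataset construction, Lasso
    feature selection with permutation feature relevance, Lasso / support
    vector / Gaussian process regressors with subject-stratified
    cross-validation, and evaluation of absolute accuracy (mean error,
    error standard deviation) and trending ability (four-quadrant and
    polar-plot concordance). Includes a seeded synthetic generator of
    paired PPG and arterial-pressure recordings with anesthesia-induction
    style blood-pressure swings for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    withr,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    kernlab
Config/testthat/edition: 3
RoxygenNote: 7.3.3
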