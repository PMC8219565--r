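Package: modeeffects
Title: Selection, Measurement, and Prediction Bias in Mixed-Mode Cognitive Assessments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to evaluate mode effects in mixed-mode cognitive
    large-scale assessments: a synthetic-study generator emulating a
    three-arm mode experiment with a web-based switch path for
    nonresponders, multiple imputation of covariates by chained
    equations, mode-specific nonresponse modelling with inverse
    participation-probability (propensity-score) weights,
    propensity-weighted one-parameter item response calibration
    (Rasch and partial credit) with weighted maximum likelihood
    person scores, differential test functioning (signed and
    unsigned) with parameter-uncertainty confidence intervals, and
    moderated regressions for mode-specific prediction bias.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    nnet,
    MASS,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
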