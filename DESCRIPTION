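Package: ocrstats
Title: Robust Estimation and Testing of Oxygen Consumption Rates from
    Extracellular Flux Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation and statistical comparison of cellular oxygen
    consumption rates (OCR) measured in multi-well extracellular flux
    (Seahorse XF) mitochondrial stress tests. Fits a within-plate
    log-linear fixed-effects model of OCR with per-well effects,
    automatically removes well-level and single-point outliers by
    iterative refitting with robust (median/MAD) thresholds, derives
    ratio-based bioenergetic metrics and natural-scale bioenergetic
    measures, corrects systematic plate-interval effects anchored on a
    control biosample, tests samples against plate-matched controls
    across plates with a pooled-variance linear model, and supports
    power analysis via minimal detectable effects and well
    subsampling. Includes the vendor-style Extreme Differences
    estimator as a baseline and a synthetic plate simulator with
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
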