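Package: oxicam
Title: Smartphone Camera Oximetry: Synthetic Cohorts, Signal Extraction,
    CNN Regression and Screening Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for camera-based pulse oximetry research. Simulates
    varied-FiO2 study cohorts (stair-stepped SpO2 descents, optically
    consistent three-channel reflectance photoplethysmograms, camera-rendered
    frames with per-channel gains and 8-bit clipping, 1 Hz reference
    readings), extracts frame-mean PPG traces, cuts fixed-length labeled
    windows, trains a small convolutional network that regresses SpO2 from
    3 s of RGB signal under leave-one-subject-out cross-validation, provides
    a classical ratio-of-ratios baseline with linear calibration, and
    evaluates both with regression metrics, Bland-Altman agreement, hypoxemia
    screening ROC analysis, label-floor ablation, and paired signed-rank
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
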