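Package: toeinkam
Title: Synthesizing Toe-In Gait and Predicting Knee Adduction Moment Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying toe-in gait retraining as an intervention for
    medial knee osteoarthritis. Learns per-degree offset patterns of the knee
    joint center and foot center of pressure between baseline and toe-in
    walking, smooths them with basis splines, and applies them to new
    subjects' baseline gait to synthesize toe-in trials. Computes the external
    knee adduction moment (KAM) with the quasi-static lever-arm method,
    normalized to percent body weight times height, and fits a standardized
    linear model that predicts first-peak KAM reduction from six clinical
    features (height, weight, walking speed, static knee alignment, baseline
    foot progression angle, and target toe-in angle). Includes a synthetic
    treadmill-gait cohort simulator with known ground truth so every pipeline
    stage can be validated without access to private motion-capture datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    signal,
    splines,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
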