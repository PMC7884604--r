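Package: bariconn
Title: Seed-Based Resting-State Connectivity and Weight-Change Prediction
    After Bariatric Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for seed-based resting-state functional connectivity
    analysis of longitudinal cohorts undergoing bariatric surgery: nuisance
    regression with motion censoring and simultaneous band-pass filtering,
    seed-to-voxel Fisher-z connectivity maps, group-by-time cluster inference
    with a permutation extent null and cluster-level FDR, leave-one-
    participant-out prediction of weight change from ROI connectivity with
    permutation chance intervals, and leptin-per-kilogram-body-fat hormone
    correlation statistics. Includes a synthetic cohort and BOLD-run
    generator with planted, configurable effect structure so that every
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
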