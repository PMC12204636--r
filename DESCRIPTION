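Package: roca
Title: Drawing-Based Cognitive Screening with a Convolutional Sketch
    Classifier and Screening-Test Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for a three-task drawing battery used in remote cognitive
    screening (wireframe cube copy, overlapping infinities, clock drawing at
    ten past five). Provides stroke-level drawing records with lossless JSON
    serialization, rasterization and size/centering preprocessing, a synthetic
    drawing generator with parametric impairment-like distortions, a compact
    fire-module convolutional sketch classifier trainable on a desktop CPU,
    the 2/1/5-point scoring rubric with threshold-based screening decisions,
    cohort simulation with a closed-form performance oracle, and a screening
    validation toolkit: confusion matrices and screening metrics, a
    random-classifier chance baseline, ROC curves with AUC and Youden-index
    threshold selection, percentile-bootstrap confidence intervals and
    p-values, threshold sweeps optimizing sensitivity and negative predictive
    value, covariate and interaction regressions on the battery score, and
    Hanley-McNeil AUC-based sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
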