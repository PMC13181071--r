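Package: drfusion
Title: Decision-Level Ensemble Fusion for Diabetic Retinopathy Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for combining the outputs of several binary classifiers
    into a single screening decision, motivated by automated diabetic
    retinopathy detection from fundus images. Implements seven decision-level
    fusion operators over per-classifier probability (or logit) panels --
    hard majority voting, soft (average-probability) voting, weighted soft
    voting, rank-based fusion, Choquet and Sugeno fuzzy-integral fusion with
    a Sugeno lambda-measure, and average-logits fusion -- together with
    decision-threshold optimization, confusion-matrix screening metrics,
    ROC-AUC, kernel-density calibration diagnostics with a decision-margin
    summary, contrast-limited adaptive histogram equalization (CLAHE) for
    image preprocessing, and a synthetic-panel generator for controlled
    experiments. A command-line interface exposes the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
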