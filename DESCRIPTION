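Package: vepnet
Title: Ensemble Neural Networks for Protein Variant Effect Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts whether a single amino-acid substitution changes a
    protein's molecular function. Implements sliding-window sequence feature
    encoding with delta features, homology-aware cross-validation built on
    single-linkage clustering of a sequence-similarity graph, balanced
    ensemble training of two-output feed-forward neural networks with
    cross-training early stopping, greedy forward feature selection with
    backward elimination, reliability-index calibration of predictions, an
    alignment-free mode driven by a derived effect-probability substitution
    matrix, and a complete evaluation suite (per-class accuracy and coverage,
    F-measures, two-state accuracy, Matthews correlation, ROC/AUC, bootstrap
    errors, accuracy-coverage and reliability curves, and multi-method
    difficulty triage). A synthetic-data generator with a planted,
    feature-expressible effect signal makes every stage testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    methods,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    pROC,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
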