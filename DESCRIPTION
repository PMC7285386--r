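Package: strokerisk
Title: Stroke Risk Stratification with SMOTE-Balanced C4.5 Decision Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A categorical pipeline for community stroke-risk screening data:
    guideline-based six-level risk labeling (H/M/L/N/T/Y) over 16 coded
    clinical and daily-habit factors, an imbalance gate with nominal-feature
    SMOTE oversampling, a from-scratch C4.5 decision-tree learner (gain-ratio
    splits, confidence-factor pessimistic pruning), stratified cross-validated
    evaluation (precision, recall, accuracy, Cohen's kappa), extraction of
    knowledge-based IF-THEN rules from the tree, and interpretive factor
    analytics (depth profiles, a factor-pair relationship matrix, habit-level
    risk profiles). Includes a synthetic cohort generator emulating the
    marginal structure of a 5,599-person screening cohort with optional
    planted factor-risk dependencies for structure-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
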