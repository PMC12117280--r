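Package: prescriptr
Title: Prescriptive Predictor Modelling for Two-Arm Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies prescriptive predictors (treatment-selection
    moderators) of a binary remission outcome in two-arm randomized
    controlled trials. Implements T-learner counterfactual estimation of
    individual treatment effects with within-arm cross-fitting,
    leakage-free nested repeated cross-validation with fold-internal
    random-forest imputation, standardization, one-hot encoding, SMOTE
    rebalancing and elastic-net variable screening, a full evaluation
    suite (rank AUC, balanced accuracy, AUPRC, calibration, DeLong
    comparison of correlated ROC curves), and kernel SHAP attribution of
    the fitted models. A calibrated synthetic trial generator with
    planted treatment-effect moderators supports end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    glmnet,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
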