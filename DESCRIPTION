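Package: predcomply
Title: Doubly Robust Analysis of Web-Based CBT Trials with a
    Predicted-Compliance Specifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing three-arm randomized trials of guided and
    self-guided web-based cognitive behavioral therapy against treatment as
    usual under loss to follow-up. Implements GAD-7/PHQ-9/PHQ-ADS scoring and
    remission rules; a synthetic trial generator with known ground truth
    (block randomization stratified by sex and symptom severity, zero-inflated
    weekly platform usage, two follow-up waves with missing-at-random
    dropout); targeted minimum loss-based and augmented-IPW estimation of
    per-arm remission rates and symptom means with influence-curve standard
    errors; a longitudinal variant using partial follow-up; predictive mean
    matching multiple imputation with Rubin pooling; a nested cross-validated
    stacking ensemble (super learner) predicting platform compliance from
    baseline covariates; top-fraction dichotomization and arm-by-specifier
    interaction tests; and kernel Shapley plus mean-substitution proportional
    SHAP attribution of the compliance model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
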