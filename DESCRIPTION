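Package: itrlearn
Title: Individualized Treatment Rules for Multi-Arm Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation and evaluation of optimal individualized treatment
    rules (ITRs) in randomized trials with more than two arms. Implements
    l1-penalized least squares with group-lasso and hierarchical group-lasso
    (strong-hierarchy) interaction selection, adaptive contrast weighted
    learning with doubly-robust AIPW contrasts and a weighted classification
    tree, pairwise direct learning with linear decision functions, and a
    Bayesian additive regression trees (BART) rule based on a built-in
    sum-of-trees MCMC sampler. Provides inverse-probability-weighted value
    estimation, misclassification against a known optimal rule, ITR effects,
    and a benefit-risk utility trade-off, together with reproducible
    simulation settings and a synthetic blood-donor cohort generator for a
    three-arm donation-interval study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    rpart,
    xgboost,
    glmnet,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
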