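Package: subsage
Title: Sub-SAGE Feature Importance with Bootstrap Uncertainty for Tree
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Loss-based Shapley feature importance for tree-ensemble
    models with uncertainty quantification. Implements the Sub-SAGE
    estimator, a reduced-coalition variant of Shapley additive global
    importance (SAGE) that can be computed exactly for gradient-boosted
    tree ensembles from independent test data, together with paired
    nonparametric bootstrap percentile and BCa confidence intervals for
    the estimator, exact per-instance SHAP values and expected relative
    feature contribution (ERFC) scores for small-depth trees, a
    closed-form result for multiple linear regression, and a synthetic
    benchmark with known data-generating process and true-model
    Monte-Carlo oracles. Tree models are read from XGBoost-style JSON
    dumps; per-node traversal probabilities are estimated empirically
    under feature independence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
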