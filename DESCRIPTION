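Package: pepperfw
Title: Fresh-Weight Estimation for Greenhouse Sweet Pepper from Morphological Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating shoot and cumulative fruit fresh weight of
    greenhouse sweet pepper from non-destructive morphological measurements.
    Provides allometric baselines built on geometric stem-volume proxies
    (stick, cylinder, truncated cone) with linear and logistic-sigmoid scaling,
    group-wise numerical data augmentation (Gaussian perturbation for small
    groups, a variational autoencoder for larger ones) with marginal
    Kullback-Leibler quality diagnostics, a stacked weighted ensemble of
    gradient-boosted trees, random forest and a feed-forward network fitted
    under leakage-safe repeated K-fold cross-validation, and model
    interpretation by feature-group ablation and permutation-sampling Shapley
    attribution. A synthetic-data generator reproduces the multi-season
    experimental design so the whole pipeline is runnable and testable without
    access to greenhouse measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    xgboost,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    ggplot2
Config/testthat/edition: 3
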