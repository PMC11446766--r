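Package: ibasml
Title: Self-Evolving Hyperparameter Optimization with an Improved Beetle
    Antennae Search for Clinical Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Improved Beetle Antennae Search (IBAS)
    metaheuristic - piecewise chaotic-map population initialization,
    iteration-adaptive Student-t mutation, and step-halving random-walk
    refinement - together with the baseline Beetle Antennae Search, a
    23-function unimodal/multimodal benchmark registry, and an IBAS-driven
    hyperparameter evolution layer for logistic regression, support vector
    machine and gradient-boosted tree classifiers with cross-validated
    fitness.  Ships a synthetic diabetic-retinopathy-like cohort generator,
    the accompanying clinical risk-factor statistics (pooled two-sample t,
    Pearson chi-square, multivariate logistic regression with Wald
    statistics and odds ratios), threshold and ranking classifier metrics,
    and a headless one-step analysis pipeline with leakage-safe data
    cleaning and risk reporting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
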