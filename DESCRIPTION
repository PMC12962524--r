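Package: gformulaHTE
Title: Target Trial Emulation with G-Computation and Cluster-Based
    Treatment-Effect Heterogeneity Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Emulates a target randomized trial from observational
    cohort data and estimates average and individual treatment effects
    by outcome-regression G-computation, with a cross-validated
    stacking ensemble (Super Learner) over generalized linear models,
    random forests, neural networks, adaptive-spline regressions, and
    gradient boosting as the outcome model. Heterogeneous subgroups are
    discovered by standardizing the individual treatment effects,
    clustering them with Ward's method (Ward.D2, Euclidean distance),
    selecting the number of clusters with Beale's index, and ranking
    candidate effect modifiers by between-cluster covariate z-score
    differences. Includes bootstrap confidence intervals, risk ratios,
    numbers needed to treat, E-value sensitivity analyses, iterative
    random-forest imputation of missing covariates, and a seeded
    synthetic-cohort generator with known ground-truth effects for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    nnet,
    pracma,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
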