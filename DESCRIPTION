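Package: fireMEV
Title: Bayesian Spatiotemporal Models for Wildfire Counts, Burned Areas, and
    Finite-Sample Maxima
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Zero-inflated count models and heavy-tailed burned-area models
    with spatially varying nonlinear covariate effects over a nested
    ecoregion hierarchy, combined into posterior predictive distributions of
    finite-sample burned-area maxima (a metastatistical extreme-value
    approach). Provides a synthetic data generator with known parameters,
    deterministic preprocessing of fire catalogs and covariate panels,
    sparse B-spline design matrices with hierarchical region interactions,
    regularized-horseshoe and AR(1)xICAR prior kernels, an adaptive
    Hamiltonian Monte Carlo sampler, and posterior predictive checking,
    holdout interval coverage, and extreme-value summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    splines,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'priors.R'
    'size-models.R'
    'count-models.R'
    'posterior.R'
    'hmc.R'
    'fit.R'
    'diagnostics.R'
    'predict.R'
    'extremes.R'
    'synthetic-fires.R'
    'evaluation.R'
    'recovery.R'
    'calibration.R'
    'splines.R'
    'design.R'
    'fireMEV-package.R'
    'hierarchy.R'
    'preprocess.R'
    'io.R'
    'synthetic-covariates.R'
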