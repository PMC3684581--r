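Package: sdmEnsemble
Title: Ensemble Species Distribution Modelling with Prevalence Weighting,
    Uncertainty Mapping and Niche Overlap Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for presence/background species distribution modelling of
    invasive species under climate change, with explicit treatment of three
    sources of predictive uncertainty: the assumed species prevalence, the
    statistical model family, and niche differentiation between invasive
    lineages. Implements prevalence weighting of background samples, forward
    variable selection with a collinearity filter, eight suitability model
    families behind one S4 interface (GAM, quadratic GLM, CART, boosted
    regression trees, BIOCLIM, DOMAIN, Mahalanobis distance, and a
    regularized presence/background exponential model), repeated-split AUC /
    sensitivity / specificity evaluation with threshold selection, consensus
    and between-model variance maps, four-class range-change projection, and
    an Outlying Mean Index analysis of niche position, breadth and
    specialization. A virtual-species simulator generates correlated
    environmental grids, logistic true-suitability surfaces and clade pairs
    with offset niche optima so the full pipeline can be validated against
    known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    rpart,
    xgboost,
    jsonlite,
    yaml,
    withr,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
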