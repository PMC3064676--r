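Package: nichecast
Title: Hierarchical Ensemble Species Distribution Modelling with Niche-Truncation-Aware Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ensemble species distribution modelling under climate
    change when a species' realized range has been truncated by human land
    use, so that its fundamental climatic niche is wider than the occupied
    one. Provides a virtual-island simulator with tree and bird species of
    known fundamental niches, derivation of ten bioclimatic predictors from
    monthly climate grids, bilinear downscaling of coarse climate anomalies,
    five suitability learners (classification trees, neural networks,
    mixture discriminant analysis, boosted trees, random forests) with
    pseudo-absence sampling and split-sample AUC/TSS evaluation, rank-based
    geometric-decay consensus forecasting, three binarization thresholds
    (TSS-maximizing, lowest presence threshold, and a coppice-informed
    lowest presence threshold approximating the fundamental niche), a
    two-stage habitat-then-bird modelling pipeline, and range-change
    metrics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    rpart,
    nnet,
    mclust,
    randomForest,
    xgboost,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
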