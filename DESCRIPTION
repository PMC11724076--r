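Package: mrep
Title: Multi-Representation Image Transformation of Tabular Data for
    Convolutional Classifiers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts tabular numeric data (bulk or single-cell expression
    matrices, or any samples-by-features table) into one or more image
    representations by embedding the features of the transposed data matrix
    into the plane with a manifold technique (t-SNE under several distance
    metrics, UMAP, PCA or kernel PCA), aligning the point cloud with its
    minimum-area bounding rectangle, and discretising feature locations onto
    a pixel grid. Sample values are painted at the frozen per-feature pixel
    locations, optionally enhanced with Gaussian blurring or a Gabor filter
    bank, and the pooled image stacks train a compact convolutional network.
    Unseen samples are classified by soft voting: per-representation class
    probabilities are averaged and the arg-max taken. Includes generators for
    the ringnorm and Madelon-style synthetic benchmarks, stratified
    train/validation/test splitting, tuned baseline classifiers (random
    forest, L2 logistic regression, level- and leaf-wise gradient-boosted
    trees) and an experiment runner for benchmark comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    Rtsne,
    uwot,
    kernlab,
    EBImage,
    randomForest,
    glmnet,
    xgboost,
    jsonlite,
    yaml,
    digest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    class,
    optparse
Config/testthat/edition: 3
biocViews: Classification, DimensionReduction, SingleCell, Transcriptomics,
    Software
RoxygenNote: 7.3.3
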