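Package: omicfuse
Title: Multi-Task Deep Learning for Multi-Omics Data Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Integrates multiple omics data modalities (expression, copy
    number, methylation, and similar feature-by-sample tables) into shared
    low-dimensional sample embeddings using multi-modal neural network
    encoders with early or intermediate fusion, trained jointly against any
    mixture of regression, classification, and Cox proportional-hazards
    survival objectives. Includes leakage-safe train/test harmonization,
    Laplacian-score feature selection, Bayesian (Gaussian-process) sequential
    hyperparameter optimization, fine-tuning for distribution shift,
    paired-bootstrap model comparison, integrated-gradients and GradientSHAP
    marker discovery, post-hoc batch alignment of embeddings (reciprocal-PCA
    mutual nearest neighbors and optimal transport), clustering utilities,
    and a synthetic multi-omics data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    cluster,
    igraph,
    survival,
    randomForest,
    e1071,
    xgboost,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
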