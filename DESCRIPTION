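Package: morphoreg
Title: Imbalanced Contrastive Regression and Structured Pruning for
    Image-Based Fish Biometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates fish biometric parameters (total length and body
    weight) from images with a lightweight convolutional regression
    network built and trained natively in R. Provides an adaptive
    contrastive regularizer for imbalanced multi-target regression that
    selects positive and negative pairs by label distance and weights
    repulsion by label density, an efficient-channel-attention regression
    head with an adaptive one-dimensional kernel, and dependency-graph
    structured channel pruning with group-level sparsity training and
    fine-tuning. Includes a seeded synthetic fish-image generator with
    long-tailed allometric length-weight labels, a two-view augmentation
    pipeline, stratified splitting, physical-unit regression metrics, and
    static parameter/FLOP accounting.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
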