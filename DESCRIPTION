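Package: scEmbedQC
Title: Statistical Quality Control and Hyperparameter Optimization for
    2D Single-Cell Embeddings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Per-cell diagnostics for two-dimensional embeddings (t-SNE,
    UMAP) of single-cell expression data. Each cell receives a reliability
    score, the Pearson correlation between its ordered mid-range
    neighborhood distances before and after the 2D embedding, and is
    called dubious or trustworthy against a permutation null distribution
    obtained by independently shuffling every gene across cells.
    Embedding hyperparameters (t-SNE perplexity; UMAP n.neighbors and
    min.dist) are optimized by minimizing the number of dubious cell
    embeddings over a candidate grid, with an alternative elbow-point
    (kneedle) selection. Includes KNN/KNC neighborhood-preservation
    metrics and a synthetic clustered-data generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rtsne,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    SummarizedExperiment,
    cluster,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, DimensionReduction, QualityControl, Visualization
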