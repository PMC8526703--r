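Package: netimg
Title: Network-Image Classification of Tumor Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates a protein-protein interaction (PPI) network with bulk
    gene expression profiles to classify tumor samples. Differentially
    expressed genes are called per cancer type with an empirical-Bayes
    moderated t-statistic, the maximum connected DEG subnetwork is embedded
    into a fixed 2D grid via the two smallest non-zero eigenpairs of the graph
    Laplacian, per-sample expression is painted onto the grid to form network
    images, and a small convolutional neural network classifies normal tissue
    versus tumor types. Includes repeated-split evaluation (error-frequency
    bookkeeping, confusion matrices, expression-similarity analysis of
    misclassified samples), survival-association summaries, and a synthetic
    cohort generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
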