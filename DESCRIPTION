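Package: hofcn
Title: High-Order Functional Connectivity Networks and Broad Learning for
    Brain-Network Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds low-order functional connectivity networks from ROI
    (region-of-interest) fMRI time series via Pearson correlation,
    constructs hypergraph-based high-order connectivity networks from
    k-nearest-neighbour hyperedges (incidence matrix, degree matrices,
    hypergraph Laplacians and the normalized association operator),
    reduces the resulting high-dimensional features with a stacked
    autoencoder trained on reconstruction error, and classifies subjects
    with a Broad Learning System whose output weights are solved in
    closed form by ridge regression. Includes a synthetic multi-subject
    two-class time-series generator with block correlation structure,
    stratified repeated k-fold cross-validation with standard
    classification metrics, and readers and writers for delimited
    time-series tables and subject manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
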