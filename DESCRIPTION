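Package: cytodr
Title: Benchmarking Dimension Reduction Methods for Mass Cytometry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scalable evaluation framework for two-dimensional embeddings of
    mass cytometry (CyTOF) data. Scores embeddings produced by any dimension
    reduction back-end with metrics in four categories (global structure
    preservation via point-cluster distances, local neighborhood preservation,
    downstream clustering performance, and concordance with a matched
    scRNA-seq reference), measures bootstrap stability, and aggregates metric
    ranks through an equal-weight hierarchy with complementarity analysis.
    Includes a probabilistic CyTOF simulator with ground-truth cell types,
    differentiation trees and pseudotime, a pluggable registry of dimension
    reduction adapters with failure capture and a subsample-fit-then-map
    policy, and FCS/CSV input handling with arcsinh preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    mclust,
    randomForest,
    FNN,
    RANN,
    Rtsne,
    uwot,
    kernlab,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    fitdistrplus,
    optparse
Config/testthat/edition: 3
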