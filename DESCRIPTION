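Package: celltaxa
Title: Cell-Type Taxonomy Pipeline for Single-Cell RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end, reproducible pipeline for building a cell-type
    taxonomy from droplet-based single-cell RNA-seq count matrices: cell and
    gene quality control, depth normalization with log2 transform,
    dispersion-based highly-variable-gene selection with curated exclusion
    lists, principal-component embedding with a pluggable batch-correction
    hook, cosine k-nearest-neighbor graph construction, graph community
    detection with iterative subclustering, Gaussian-mixture assignment of
    clusters to neuronal/non-neuronal and neurotransmitter classes, one-vs-rest
    AUROC marker discovery with a Wilcoxon cross-check, and a marker-panel
    sufficiency experiment using a random-forest classifier. Ships a
    negative-binomial count simulator with planted ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
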