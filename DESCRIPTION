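Package: gcnTransfer
Title: Cell-Type Label Transfer Across Single-Cell Datasets with Graph
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers cell-type labels from a labeled reference single-cell
    expression matrix to an unlabeled query dataset, across platforms, species
    and omics layers. A hybrid cell graph is built from mutual nearest
    neighbors in a canonical-correlation space (inter-dataset edges) together
    with an intra-query mutual-kNN graph, and a semi-supervised two-layer
    graph convolutional network is trained on the reference labels to predict
    query labels. Includes ANOVA-based feature selection, per-gene
    standardization, screening of putative unknown cell types by entropy and
    enrichment of inter-dataset graph links over modularity clusters,
    one-to-one homolog mapping for cross-species runs, evaluation metrics
    (accuracy, batch-mixing entropy, silhouette widths), and a synthetic-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    cluster,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
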