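Package: crossmed
Title: Cross-Tissue Endocrine Mediator Screening and Single-Cell Divergence Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A systems-genetics toolkit for discovering candidate endocrine
    mediators between tissues. Ranks secreted origin-tissue genes by their
    aggregate biweight-midcorrelation coupling (the S_sec crosstalk score)
    with a target-tissue transcriptome across a genetic reference panel,
    builds gene-centric cross-tissue FDR profiles, and quantifies
    per-cell-type transcriptional divergence between conditions in
    single-nucleus RNA-seq data with a permutation null on centroid
    Euclidean distances. Includes seeded synthetic-data generators for
    strain-panel expression and multi-cell-type count data with planted
    structure, so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
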