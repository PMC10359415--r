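Package: senescreen
Title: Single-Cell Senescence Scoring, Regulon Dynamics and
    Transcriptome-Proteome Integration for MSC Products
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies progressive cellular senescence across single-cell
    clusters of cultured mesenchymal stromal cells (MSCs) and nominates
    candidate regulator transcription factors by integrating single-cell
    transcriptomes with bulk proteomes. Implements average-expression
    gene-set scoring, cell-cycle phase assignment with expression-matched
    control genes, pseudobulk construction with negative-binomial Wald
    differential expression (batch-aware, Benjamini-Hochberg corrected),
    rank-based regulon activity via the area under the recovery curve,
    per-stage transition linear models over a branching cluster graph,
    in-silico-bulk/proteome merging with quantile normalization and PCA,
    two-dimensional annotation enrichment, and a dual-omics transcription
    factor candidate screen. Ships a synthetic-data generator that plants
    known ground truth (programs, regulons, a master TF, tissue-group
    differences) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    SingleCellExperiment,
    limma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
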