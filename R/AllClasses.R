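#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SummarizedExperiment assay assays assayNames colData colData<- rowData
#' @importFrom SingleCellExperiment SingleCellExperiment
NULL

#' Single-cell UMI count container
#'
#' A thin wrapper around [SingleCellExperiment::SingleCellExperiment] holding
#' raw UMI counts (genes in rows, cells in columns) together with per-cell
#' metadata. Validity enforces non-negative integer counts, unique gene and
#' cell identifiers, and a `sample_id` and `batch` for every cell. Optional
#' per-cell columns are `tissue_group` (e.g. `"perinatal"` / `"adult"`),
#' `cluster` and `phase`.
#'
#' @slot ... see [SingleCellExperiment::SingleCellExperiment].
#' @export
setClass("CellMatrix", contains = "SingleCellExperiment")

.validCellMatrix <- function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (min(cts) < 0) msg <- c(msg, "counts must be non-negative")
        v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.vector(cts)
        if (length(v) && max(abs(v - round(v))) > 1e-8)
            msg <- c(msg, "counts must be integer-valued UMIs")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "cell ids must be present and unique")
    cd <- colData(object)
    for (req in c("sample_id", "batch")) {
        if (!req %in% colnames(cd) || anyNA(cd[[req]]))
            msg <- c(msg, sprintf("every cell needs a non-missing '%s'", req))
    }
    if ("cluster" %in% colnames(cd)) {
        cl <- as.character(cd$cluster)
        if (any(!is.na(cl) & !nzchar(cl)))
            msg <- c(msg, "cluster labels, when present, must be non-empty strings")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("CellMatrix", .validCellMatrix)

#' Construct a CellMatrix
#'
#' @param counts genes x cells matrix (dense or sparse) of non-negative
#'   integer UMI counts, with unique row (gene) and column (cell) names.
#' @param cellData data.frame or DataFrame of per-cell metadata with at least
#'   `sample_id` and `batch`; rows match columns of `counts` (by `cell_id`
#'   column or rownames when present, otherwise by position).
#' @return A [CellMatrix-class] object.
#' @examples
#' cts <- matrix(rpois(12, 2), 3, 4,
#'               dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cm <- CellMatrix(cts, data.frame(sample_id = "s1", batch = "b1",
#'                                  row.names = colnames(cts)))
#' @export
CellMatrix <- function(counts, cellData) {
    counts <- as(counts, "CsparseMatrix")
    cellData <- as.data.frame(cellData)
    if ("cell_id" %in% colnames(cellData)) {
        rownames(cellData) <- cellData$cell_id
        cellData$cell_id <- NULL
    }
    if (!is.null(rownames(cellData)) &&
        !identical(rownames(cellData), as.character(seq_len(nrow(cellData))))) {
        missing <- setdiff(colnames(counts), rownames(cellData))
        if (length(missing)) {
            stop("cells present in counts but absent from metadata: ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
        }
        cellData <- cellData[colnames(counts), , drop = FALSE]
    } else if (nrow(cellData) != ncol(counts)) {
        stop("metadata has ", nrow(cellData), " rows but counts has ",
             ncol(counts), " cells")
    }
    methods::new("CellMatrix",
                 SingleCellExperiment(assays = list(counts = counts),
                                      colData = DataFrame(cellData)))
}

setMethod("show", "CellMatrix", function(object) {
    cat(sprintf("CellMatrix: %d genes x %d cells\n", nrow(object), ncol(object)))
    cd <- colData(object)
    cat(" samples:", length(unique(cd$sample_id)),
        "| batches:", length(unique(cd$batch)))
    if ("cluster" %in% colnames(cd))
        cat(" | clusters:", length(unique(cd$cluster)))
    cat("\n assays:", paste(assayNames(object), collapse = ", "), "\n")
})

#' Named gene set
#'
#' @slot name set name (for a regulon read from GMT, the transcription factor).
#' @slot genes unique gene identifiers; non-empty.
#' @slot description free-text description.
#' @export
setClass("GeneSet", representation(name = "character", genes = "character",
                                   description = "character"))
setValidity("GeneSet", function(object) {
    msg <- NULL
    if (length(object@genes) == 0) msg <- c(msg, "gene set must be non-empty")
    if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate gene ids in set")
    if (length(object@name) != 1L) msg <- c(msg, "name must be a single string")
    if (is.null(msg)) TRUE else msg
})

#' @rdname GeneSet-class
#' @param name,genes,description slots; see class description.
#' @export
GeneSet <- function(name, genes, description = "") {
    methods::new("GeneSet", name = name, genes = unique(as.character(genes)),
                 description = description)
}
setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet '%s' (%d genes)\n", object@name, length(object@genes)))
})

#' Regulon: a transcription factor and its target genes
#'
#' @slot tf transcription factor gene id.
#' @slot targets unique target gene ids; the TF itself need not be a target.
#' @export
setClass("Regulon", representation(tf = "character", targets = "character"))
setValidity("Regulon", function(object) {
    msg <- NULL
    if (length(object@targets) == 0) msg <- c(msg, "regulon must have targets")
    if (anyDuplicated(object@targets)) msg <- c(msg, "duplicate target ids")
    if (length(object@tf) != 1L) msg <- c(msg, "tf must be a single gene id")
    if (is.null(msg)) TRUE else msg
})

#' @rdname Regulon-class
#' @param tf,targets slots; see class description.
#' @export
Regulon <- function(tf, targets) {
    methods::new("Regulon", tf = tf, targets = unique(as.character(targets)))
}
setMethod("show", "Regulon", function(object) {
    cat(sprintf("Regulon %s (%d targets)\n", object@tf, length(object@targets)))
})

#' Branching stage-transition graph over cell clusters
#'
#' Directed acyclic graph whose nodes are cluster/stage labels; every
#' non-root stage has exactly one parent. Stage order is deterministic
#' (topological, ties broken by label).
#'
#' @slot stages ordered stage labels.
#' @slot edges data.frame with columns `parent`, `child`.
#' @slot roots stages with no parent.
#' @export
setClass("TransitionGraph",
         representation(stages = "character", edges = "data.frame",
                        roots = "character"))
setMethod("show", "TransitionGraph", function(object) {
    cat(sprintf("TransitionGraph: %d stages (%s), %d edges, roots: %s\n",
                length(object@stages), paste(object@stages, collapse = " "),
                nrow(object@edges), paste(object@roots, collapse = ", ")))
})

#' Construct a TransitionGraph from an edge list
#'
#' @param edges data.frame with columns `parent`, `child`; the reserved
#'   parent label `"ROOT"` declares a root stage.
#' @return A validated [TransitionGraph-class].
#' @export
TransitionGraph <- function(edges) {
    edges <- as.data.frame(edges)
    if (!all(c("parent", "child") %in% colnames(edges)))
        stop("edge list needs columns 'parent' and 'child'")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
    real <- edges[edges$parent != "ROOT", , drop = FALSE]
    stages <- unique(c(real$parent, real$child,
                       edges$child[edges$parent == "ROOT"]))
    if (anyDuplicated(real$child))
        stop("stage with two parents: ",
             paste(unique(real$child[duplicated(real$child)]), collapse = ", "))
    parent_of <- stats::setNames(real$parent, real$child)
    roots <- sort(setdiff(stages, names(parent_of)))
    if (length(stages) && !length(roots)) stop("transition graph has a cycle")
    ## Kahn topological order, ties by label
    order <- character(0)
    avail <- sort(roots)
    remaining <- real
    while (length(avail)) {
        s <- avail[1]; avail <- avail[-1]
        order <- c(order, s)
        kids <- sort(remaining$child[remaining$parent == s])
        remaining <- remaining[remaining$parent != s, , drop = FALSE]
        avail <- sort(c(avail, kids))
    }
    if (length(order) != length(stages)) stop("transition graph has a cycle")
    methods::new("TransitionGraph", stages = order,
                 edges = real[, c("parent", "child")], roots = roots)
}

#' Bulk proteome intensity container
#'
#' A [SummarizedExperiment::SummarizedExperiment] with assay `intensity`
#' (non-negative peak areas, proteins x samples), a `gene_id` rowData column
#' recording the protein-to-gene mapping, and per-sample `group` metadata.
#'
#' @export
setClass("ProteomeTable", contains = "SummarizedExperiment")
setValidity("ProteomeTable", function(object) {
    msg <- NULL
    if (!"intensity" %in% assayNames(object))
        msg <- c(msg, "assay 'intensity' is required")
    else if (min(assay(object, "intensity")) < 0)
        msg <- c(msg, "intensities must be non-negative")
    if (!"gene_id" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData column 'gene_id' (protein-to-gene map) is required")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (!"group" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'group' is required")
    if (is.null(msg)) TRUE else msg
})

#' @rdname ProteomeTable-class
#' @param intensities proteins x samples non-negative matrix with protein ids
#'   as rownames and sample ids as colnames.
#' @param geneIds character vector mapping each protein row to a gene symbol.
#' @param sampleData data.frame with at least a `group` column, one row per
#'   sample.
#' @export
ProteomeTable <- function(intensities, geneIds, sampleData) {
    intensities <- as.matrix(intensities)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = intensities),
        rowData = DataFrame(gene_id = as.character(geneIds)),
        colData = DataFrame(as.data.frame(sampleData)))
    methods::new("ProteomeTable", se)
}
setMethod("show", "ProteomeTable", function(object) {
    cat(sprintf("ProteomeTable: %d proteins x %d samples (groups: %s)\n",
                nrow(object), ncol(object),
                paste(unique(colData(object)$group), collapse = ", ")))
})

#' Pseudobulk count container
#'
#' Genes x pseudobulk-unit summed UMI counts. Each unit is a sample (in-silico
#' bulk) or a sample-cluster combination, with `sample_id`, optional
#' `cluster`, `group`, `batch` and `n_cells` in `colData`. Size factors (see
#' [computeSizeFactors()]) live in `colData$size_factor`.
#'
#' @export
setClass("PseudobulkTable", contains = "SummarizedExperiment")
setValidity("PseudobulkTable", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else if (min(assay(object, "counts")) < 0)
        msg <- c(msg, "counts must be non-negative")
    if (!"sample_id" %in% colnames(colData(object)))
        msg <- c(msg, "colData column 'sample_id' is required")
    if ("size_factor" %in% colnames(colData(object)) &&
        any(colData(object)$size_factor <= 0))
        msg <- c(msg, "size factors must be positive")
    if (is.null(msg)) TRUE else msg
})
setMethod("show", "PseudobulkTable", function(object) {
    cat(sprintf("PseudobulkTable: %d genes x %d units\n",
                nrow(object), ncol(object)))
    cd <- colData(object)
    if ("cluster" %in% colnames(cd))
        cat(" grouped by sample x cluster\n") else cat(" in-silico bulk (by sample)\n")
})

#' Merged dual-omics expression container
#'
#' Genes x samples matrix spanning both modalities after the per-modality
#' transforms and quantile normalization; `colData` carries `modality`
#' (`"rna"`/`"protein"`), `group` and `source_sample`.
#'
#' @export
setClass("OmicsPair", contains = "SummarizedExperiment")
setValidity("OmicsPair", function(object) {
    msg <- NULL
    cd <- colData(object)
    if (!all(c("modality", "group", "source_sample") %in% colnames(cd)))
        msg <- c(msg, "colData needs modality, group, source_sample")
    else if (!all(cd$modality %in% c("rna", "protein")))
        msg <- c(msg, "modality must be 'rna' or 'protein'")
    if (is.null(msg)) TRUE else msg
})
setMethod("show", "OmicsPair", function(object) {
    cd <- colData(object)
    cat(sprintf("OmicsPair: %d shared genes; %d rna + %d protein samples\n",
                nrow(object), sum(cd$modality == "rna"),
                sum(cd$modality == "protein")))
})

#' Regulon-by-stage transition statistics
#'
#' Holds the t-values and p-values of the per-stage transition linear models
#' (each non-root stage contrasted against its parent; each root stage
#' against all other cells), BH-adjusted within each stage.
#'
#' @slot tValues regulons x stages t-statistic matrix.
#' @slot pValues matching two-sided p-values.
#' @slot pAdjusted BH adjustment of `pValues`, within each stage column.
#' @slot graph the [TransitionGraph-class] the contrasts were computed on.
#' @export
setClass("TransitionTable",
         representation(tValues = "matrix", pValues = "matrix",
                        pAdjusted = "matrix", graph = "TransitionGraph"))
setMethod("show", "TransitionTable", function(object) {
    cat(sprintf("TransitionTable: %d regulons x %d stages (max |t| = %.1f)\n",
                nrow(object@tValues), ncol(object@tValues),
                max(abs(object@tValues))))
})
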