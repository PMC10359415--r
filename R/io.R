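## Readers and writers for the on-disk formats used across the pipeline:
## MatrixMarket triples (+ per-cell metadata CSV), dense CSV count tables,
## GMT gene sets / regulons, TSV edge lists, and proteome intensity CSVs.

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

.log <- function(level, ...) {
    threshold <- getOption("senescreen.log_level", "info")
    if (.log_levels[[level]] >= .log_levels[[threshold]])
        message(sprintf("[%s] %s", level, paste0(...)))
    invisible(NULL)
}

.read_tsv_col <- function(path, col = 1L) {
    x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    as.character(x[[min(col, ncol(x))]])
}

.find_one <- function(dir, stem) {
    for (f in c(stem, paste0(stem, ".gz")))
        if (file.exists(file.path(dir, f))) return(file.path(dir, f))
    stop("expected ", stem, "[.gz] in ", dir)
}

#' Read a single-cell UMI count matrix
#'
#' Accepts either a directory holding a MatrixMarket triple
#' (`matrix.mtx[.gz]`, `features.tsv[.gz]`, `barcodes.tsv[.gz]`; genes in
#' rows as written by common droplet pipelines) or a dense CSV with cells in
#' rows, a header row of gene ids and the cell id in the first column.
#' Per-cell metadata is read from `metaPath` (CSV/TSV with a `cell_id`
#' column plus at least `sample_id` and `batch`); cells present in the
#' counts but absent from the metadata raise an error naming the first ten
#' offenders.
#'
#' @param path directory (MTX triple) or CSV file.
#' @param metaPath metadata file; defaults to `meta.csv` inside `path` when
#'   `path` is a directory.
#' @return A [CellMatrix-class].
#' @export
readCellMatrix <- function(path, metaPath = NULL) {
    if (dir.exists(path)) {
        mtx <- .find_one(path, "matrix.mtx")
        counts <- tryCatch(as(Matrix::readMM(mtx), "CsparseMatrix"),
                           error = function(e)
                               stop("malformed MatrixMarket file '", mtx,
                                    "': ", conditionMessage(e)))
        feats <- .read_tsv_col(.find_one(path, "features.tsv"))
        bcs <- .read_tsv_col(.find_one(path, "barcodes.tsv"))
        if (nrow(counts) != length(feats) || ncol(counts) != length(bcs))
            stop(sprintf(paste0("dimension mismatch: matrix is %d x %d but ",
                                "features.tsv has %d rows and barcodes.tsv %d"),
                         nrow(counts), ncol(counts), length(feats), length(bcs)))
        if (anyDuplicated(bcs))
            stop("duplicate barcodes: ",
                 paste(utils::head(unique(bcs[duplicated(bcs)]), 10),
                       collapse = ", "))
        dimnames(counts) <- list(feats, bcs)
        if (is.null(metaPath)) metaPath <- file.path(path, "meta.csv")
    } else {
        tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
        counts <- t(as.matrix(tab))   # cells in rows on disk -> genes in rows
        if (is.null(metaPath)) stop("metaPath is required for dense CSV input")
    }
    counts <- round(counts)
    meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
    if (!"cell_id" %in% colnames(meta))
        stop("metadata must have a 'cell_id' column")
    if (anyDuplicated(meta$cell_id))
        stop("duplicate cell ids in metadata")
    .log("info", sprintf("read %d genes x %d cells from %s",
                         nrow(counts), ncol(counts), path))
    CellMatrix(counts, meta)
}

#' Write a CellMatrix as a MatrixMarket triple plus metadata CSV
#'
#' @param cm a [CellMatrix-class].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` and `meta.csv`.
#' @return `dir`, invisibly.
#' @export
writeCellMatrix <- function(cm, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(as(assay(cm, "counts"), "CsparseMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(cm), file.path(dir, "features.tsv"))
    writeLines(colnames(cm), file.path(dir, "barcodes.tsv"))
    meta <- cbind(cell_id = colnames(cm),
                  as.data.frame(colData(cm)))
    utils::write.csv(meta, file.path(dir, "meta.csv"), row.names = FALSE,
                     quote = FALSE)
    invisible(dir)
}

#' Read gene sets (or regulons) from a GMT file
#'
#' Tab-separated lines: name, description, then member genes. Duplicate
#' genes within a line are dropped with a warning; empty lines are skipped;
#' a line with fewer than three fields is an error.
#'
#' @param path GMT file.
#' @return A named list of [GeneSet-class] objects, in file order.
#' @seealso [asRegulons()] to reinterpret sets as TF regulons.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(seq_along(lines), function(i) {
        fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(fields) < 3)
            stop("GMT line ", i, " has fewer than 3 fields")
        g <- fields[-(1:2)]
        g <- g[nzchar(g)]
        if (anyDuplicated(g)) {
            warning("duplicate genes in set '", fields[1], "' deduplicated")
            g <- unique(g)
        }
        GeneSet(fields[1], g, fields[2])
    })
    stats::setNames(sets, vapply(sets, function(s) s@name, ""))
}

#' Write gene sets (or regulons) to GMT
#'
#' @param sets list of [GeneSet-class] or [Regulon-class] objects.
#' @param path output file.
#' @export
writeGmt <- function(sets, path) {
    lines <- vapply(sets, function(s) {
        if (methods::is(s, "Regulon"))
            paste(c(s@tf, "regulon", s@targets), collapse = "\t")
        else paste(c(s@name, if (nzchar(s@description)) s@description else ".",
                     s@genes), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Reinterpret gene sets as regulons (set name = transcription factor)
#'
#' @param sets list of [GeneSet-class] objects.
#' @return A named list of [Regulon-class] objects.
#' @export
asRegulons <- function(sets) {
    regs <- lapply(sets, function(s) Regulon(s@name, s@genes))
    stats::setNames(regs, vapply(regs, function(r) r@tf, ""))
}

#' Read a stage-transition graph from a two-column edge TSV
#'
#' Columns are parent and child stage labels; the reserved parent `"ROOT"`
#' declares a root. Cycles and stages with two parents are errors; the
#' resulting stage order is topological with ties broken by label.
#'
#' @param path TSV file (no header).
#' @return A [TransitionGraph-class].
#' @export
readTransitionGraph <- function(path) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("edge list must have two columns (parent, child)")
    TransitionGraph(data.frame(parent = tab[[1]], child = tab[[2]]))
}

#' Write a TransitionGraph as an edge TSV
#'
#' @param graph a [TransitionGraph-class].
#' @param path output file.
#' @export
writeTransitionGraph <- function(graph, path) {
    edges <- rbind(data.frame(parent = "ROOT", child = graph@roots),
                   graph@edges)
    utils::write.table(edges, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read a bulk proteome intensity table
#'
#' CSV with columns `protein_id`, `gene_id`, then one column per sample;
#' sample metadata (columns `sample_id`, `group`, optionally more) in a
#' second CSV.
#'
#' @param path intensity CSV.
#' @param metaPath sample metadata CSV.
#' @return A [ProteomeTable-class].
#' @export
readProteomeTable <- function(path, metaPath) {
    tab <- utils::read.csv(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    if (!all(c("protein_id", "gene_id") %in% colnames(tab)))
        stop("proteome CSV needs 'protein_id' and 'gene_id' columns")
    m <- as.matrix(tab[, setdiff(colnames(tab), c("protein_id", "gene_id")),
                       drop = FALSE])
    rownames(m) <- tab$protein_id
    meta <- utils::read.csv(metaPath, stringsAsFactors = FALSE)
    if (!"sample_id" %in% colnames(meta)) stop("sample metadata needs 'sample_id'")
    rownames(meta) <- meta$sample_id
    meta <- meta[colnames(m), , drop = FALSE]
    ProteomeTable(m, tab$gene_id, meta[, setdiff(colnames(meta), "sample_id"),
                                       drop = FALSE])
}

#' Write a ProteomeTable to CSV (intensities + sample metadata)
#'
#' @param pt a [ProteomeTable-class].
#' @param path intensity CSV path.
#' @param metaPath sample metadata CSV path.
#' @export
writeProteomeTable <- function(pt, path, metaPath) {
    tab <- cbind(data.frame(protein_id = rownames(pt),
                            gene_id = rowData(pt)$gene_id),
                 as.data.frame(assay(pt, "intensity")))
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
    meta <- cbind(sample_id = colnames(pt), as.data.frame(colData(pt)))
    utils::write.csv(meta, metaPath, row.names = FALSE, quote = FALSE)
    invisible(path)
}
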