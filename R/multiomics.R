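## Transcriptome-proteome integration: log-CPM transform of in-silico bulk,
## quantile-normalized merge, PCA with a fixed sign convention, Pearson
## correlation matrices, and two-dimensional annotation enrichment with
## Spearman concordance across categories.

#' Log2 counts-per-million transform
#'
#' `value[g,j] = log2((count + 0.5) / (libsize + 1) * 1e6)`, the standard
#' moderated log-CPM used to put in-silico bulk counts on a scale comparable
#' with log-intensity data.
#'
#' @param x a sample-level [PseudobulkTable-class] or a genes x samples
#'   count matrix.
#' @return genes x samples numeric matrix.
#' @export
logCpm <- function(x) {
    counts <- if (methods::is(x, "PseudobulkTable")) assay(x, "counts") else as.matrix(x)
    libsize <- colSums(counts)
    if (any(libsize == 0))
        stop("zero-library column: ",
             paste(colnames(counts)[libsize == 0], collapse = ", "))
    log2(sweep(counts + 0.5, 2, libsize + 1, "/") * 1e6)
}

#' Quantile normalization
#'
#' Replaces each column's values by the across-column mean of the order
#' statistics at each rank (ties within a column receive the mean of their
#' ranks' reference values), so that every column acquires the same value
#' distribution. Idempotent. Thin wrapper over
#' [limma::normalizeQuantiles()] with `ties = TRUE`.
#'
#' @param m numeric matrix without missing values.
#' @return Matrix of the same shape and dimnames.
#' @export
quantileNormalize <- function(m) {
    m <- as.matrix(m)
    if (anyNA(m)) stop("missing values are not allowed; drop incomplete rows first")
    out <- limma::normalizeQuantiles(m, ties = TRUE)
    dimnames(out) <- dimnames(m)
    out
}

#' Merge in-silico bulk transcriptome with a bulk proteome
#'
#' Transforms the transcript side with [logCpm()] and the protein side to
#' per-sample median-centered log2 intensities, restricts both to the shared
#' gene set (proteins with duplicated or missing gene mapping are dropped,
#' logged), concatenates the samples of both modalities and quantile
#' normalizes the merged matrix.
#'
#' @param pb sample-level [PseudobulkTable-class] (see [makePseudobulk()]
#'   with `by = "sample"`).
#' @param pt a [ProteomeTable-class].
#' @return An [OmicsPair-class]; columns are `<sample>_rna` then
#'   `<sample>_protein` with `modality`, `group`, `source_sample` metadata.
#' @export
mergeOmics <- function(pb, pt) {
    rna <- logCpm(pb)
    intens <- assay(pt, "intensity")
    gene <- as.character(rowData(pt)$gene_id)
    ok <- !is.na(gene) & nzchar(gene) & !duplicated(gene)
    if (!all(ok))
        .log("info", sum(!ok), " protein row(s) with missing/duplicate gene mapping dropped")
    prot <- log2(intens[ok, , drop = FALSE] + 1)
    rownames(prot) <- gene[ok]
    prot <- sweep(prot, 2, apply(prot, 2, stats::median), "-")

    shared <- intersect(rownames(rna), rownames(prot))
    if (!length(shared)) stop("no shared genes between modalities")
    merged <- cbind(rna[shared, , drop = FALSE], prot[shared, , drop = FALSE])
    src <- c(colnames(rna), colnames(prot))
    modality <- rep(c("rna", "protein"), c(ncol(rna), ncol(prot)))
    colnames(merged) <- paste(src, modality, sep = "_")
    grp <- c(as.character(colData(pb)$group), as.character(colData(pt)$group))
    merged <- quantileNormalize(merged)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(merged = merged),
        colData = DataFrame(modality = modality, group = grp,
                            source_sample = src,
                            row.names = colnames(merged)))
    metadata(se)$transform <- c(rna = "log2 CPM (moderated)",
                                protein = "median-centered log2 intensity")
    methods::new("OmicsPair", se)
}

#' PCA of the merged dual-omics matrix
#'
#' Gene-centered singular value decomposition with samples as observations.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive, making scores reproducible bit-for-bit across runs.
#'
#' @param op an [OmicsPair-class] with at least three samples per modality.
#' @param nPc number of components to return (default 2).
#' @return list with `scores` (data.frame: PCs plus `modality` and `group`),
#'   `loadings` (genes x nPc) and `varFrac` (fraction of variance per PC,
#'   non-increasing, summing to at most 1).
#' @export
mergedPca <- function(op, nPc = 2) {
    cd <- colData(op)
    if (min(table(cd$modality)) < 3)
        stop("need at least three samples per modality")
    x <- t(assay(op, "merged"))
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    if (ncol(pc$rotation) < nPc)
        stop("matrix rank ", ncol(pc$rotation), " is below nPc = ", nPc)
    scores <- pc$x[, seq_len(nPc), drop = FALSE]
    loadings <- pc$rotation[, seq_len(nPc), drop = FALSE]
    for (j in seq_len(nPc)) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    list(scores = data.frame(scores, modality = cd$modality, group = cd$group,
                             row.names = rownames(x)),
         loadings = loadings,
         varFrac = pc$sdev^2 / sum(pc$sdev^2))
}

#' Two-dimensional annotation enrichment
#'
#' For two per-gene statistics (e.g. protein and transcript log2 fold
#' changes over the same genes), ranks genes in each dimension (ascending,
#' average ties) and scores each gene category as
#' `s = (2/n) * (mean member rank - (n+1)/2)`, a rank statistic in
#' `(-1, 1)`; `|s|` is bounded by `(n-m)/n` for `m` members among `n` genes
#' and is invariant to monotone transforms of the inputs. Per dimension, a
#' two-sided Mann-Whitney test compares members against non-members; a
#' category's combined p is `min(1, 2*min(p_x, p_y))` (factor-2 Bonferroni
#' over dimensions), BH-adjusted across categories. Spearman's correlation
#' of `s_x` versus `s_y` across tested categories summarizes
#' transcriptome-proteome concordance.
#'
#' @param x,y named numeric vectors over the same genes.
#' @param categories list of [GeneSet-class] categories; categories with
#'   fewer than `minSize` present genes are skipped (logged).
#' @param minSize minimum present members (default 3).
#' @param fdr significance threshold on the BH-adjusted combined p
#'   (default 0.05).
#' @return list with `table` (category, n, s_x, s_y, p_x, p_y, fdr,
#'   significant), `spearman_rho` and `spearman_p`.
#' @export
enrichment2d <- function(x, y, categories, minSize = 3, fdr = 0.05) {
    if (is.null(names(x)) || is.null(names(y)))
        stop("x and y must be named by gene")
    shared <- intersect(names(x), names(y))
    x <- x[shared]; y <- y[shared]
    n <- length(shared)
    rx <- rank(x); ry <- rank(y)

    rows <- lapply(categories, function(cat) {
        members <- intersect(cat@genes, shared)
        m <- length(members)
        if (m < minSize) return(NULL)
        inset <- shared %in% members
        sx <- (2 / n) * (mean(rx[inset]) - (n + 1) / 2)
        sy <- (2 / n) * (mean(ry[inset]) - (n + 1) / 2)
        px <- if (m == n) 1 else
            stats::wilcox.test(x[inset], x[!inset], exact = FALSE)$p.value
        py <- if (m == n) 1 else
            stats::wilcox.test(y[inset], y[!inset], exact = FALSE)$p.value
        data.frame(category = cat@name, n = m, s_x = sx, s_y = sy,
                   p_x = px, p_y = py)
    })
    skipped <- sum(vapply(rows, is.null, TRUE))
    if (skipped)
        .log("info", skipped, " categor(ies) below the minimum size skipped")
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) stop("no category shares at least ", minSize,
                            " genes with x/y")
    tab <- do.call(rbind, rows)
    combined <- pmin(1, 2 * pmin(tab$p_x, tab$p_y))
    tab$fdr <- stats::p.adjust(combined, "BH")
    tab$significant <- tab$fdr < fdr
    ct <- if (nrow(tab) >= 3)
        stats::cor.test(tab$s_x, tab$s_y, method = "spearman", exact = FALSE)
    else NULL
    list(table = tab,
         spearman_rho = if (is.null(ct)) NA_real_ else unname(ct$estimate),
         spearman_p = if (is.null(ct)) NA_real_ else ct$p.value)
}

#' Pearson correlation matrix between expression profiles
#'
#' Column-by-column Pearson correlations of two matrices over a shared gene
#' index (e.g. log-scale pseudobulk cluster profiles of two datasets).
#'
#' @param a,b genes x profiles matrices with rownames; `b` defaults to `a`.
#' @param method correlation method (default `"pearson"`).
#' @return `ncol(a)` x `ncol(b)` correlation matrix.
#' @export
correlationMatrix <- function(a, b = a, method = "pearson") {
    a <- as.matrix(a); b <- as.matrix(b)
    shared <- intersect(rownames(a), rownames(b))
    if (!length(shared)) stop("no shared gene index")
    a <- a[shared, , drop = FALSE]; b <- b[shared, , drop = FALSE]
    zv <- c(colnames(a)[apply(a, 2, stats::sd) == 0],
            colnames(b)[apply(b, 2, stats::sd) == 0])
    if (length(zv)) stop("zero-variance column(s): ",
                         paste(unique(zv), collapse = ", "))
    stats::cor(a, b, method = method)
}
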