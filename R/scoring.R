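## Cell-level normalization, average-expression gene-set scores, cell-cycle
## phase assignment with expression-matched control genes, and ANOVA/Tukey
## group comparisons of per-cell scores.

## evaluate expr under a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Depth-normalize UMI counts
#'
#' Scales each cell's counts to a common sequencing depth (default 10,000
#' molecules per cell) and log-transforms:
#' `value[g,c] = log1p(count[g,c] / L_c * scale)` with `L_c` the cell's
#' total UMI count. Cells with zero library size are mapped to all zeros
#' with a warning. The result is stored as assay `"logcounts"`.
#'
#' @param cm a [CellMatrix-class].
#' @param scale target depth per cell (default 10000).
#' @return `cm` with a `"logcounts"` assay added.
#' @export
normalizeCells <- function(cm, scale = 10000) {
    stopifnot(scale > 0)
    counts <- as(assay(cm, "counts"), "CsparseMatrix")
    libsize <- Matrix::colSums(counts)
    zero <- libsize == 0
    if (any(zero)) {
        warning(sum(zero), " cell(s) with zero library size mapped to zeros")
        libsize[zero] <- 1
    }
    sf <- scale / libsize
    nm <- counts
    if (length(nm@x))
        nm@x <- log1p(nm@x * rep.int(sf, diff(nm@p)))
    SummarizedExperiment::assay(cm, "logcounts") <- nm
    cm
}

.logcounts <- function(cm) {
    if (!"logcounts" %in% assayNames(cm))
        stop("no 'logcounts' assay; run normalizeCells() first")
    assay(cm, "logcounts")
}

#' Score a gene set as average normalized expression
#'
#' The functional score of a cell is the plain mean of its normalized
#' (log1p-CP10K) expression over the set's genes. Set genes absent from the
#' matrix are dropped (count logged); if no set gene is present, an error
#' names the set.
#'
#' @param cm a normalized [CellMatrix-class] (see [normalizeCells()]).
#' @param gs a [GeneSet-class].
#' @return Named numeric vector, one score per cell.
#' @export
scoreGeneSet <- function(cm, gs) {
    nm <- .logcounts(cm)
    present <- intersect(gs@genes, rownames(nm))
    if (!length(present))
        stop("no gene of set '", gs@name, "' is present in the matrix")
    dropped <- length(gs@genes) - length(present)
    if (dropped > 0)
        .log("info", sprintf("set '%s': %d absent gene(s) dropped",
                             gs@name, dropped))
    if (length(present) == 1L) return(nm[present, ])
    Matrix::colMeans(nm[present, , drop = FALSE])
}

#' Assign cell-cycle phase from S and G2M marker expression
#'
#' Each phase score is the mean normalized expression of the phase markers
#' minus the mean of expression-matched control genes. Controls are drawn
#' per marker gene, without replacement and under a fixed seed, from bins of
#' genes with similar across-cell mean expression (genes ranked by mean and
#' cut into `nBins` equal-size bins). A cell is called `S` or `G2M` by the
#' larger of the two scores when that score is positive (ties toward `S`),
#' and `G1` otherwise.
#'
#' @param cm a normalized [CellMatrix-class].
#' @param sGenes,g2mGenes [GeneSet-class] of S- and G2M-phase markers.
#' @param nBins number of expression bins (default 24).
#' @param nCtrl control genes drawn per marker gene (default 100).
#' @param seed RNG seed for the control draw.
#' @return data.frame with columns `S_score`, `G2M_score`, `phase`,
#'   one row per cell.
#' @export
scoreCellCycle <- function(cm, sGenes, g2mGenes, nBins = 24, nCtrl = 100,
                           seed = 1L) {
    nm <- .logcounts(cm)
    gene_means <- Matrix::rowMeans(nm)
    n <- length(gene_means)
    bin <- ceiling(nBins * rank(gene_means, ties.method = "first") / n)
    bin_members <- split(rownames(nm), bin)

    score_one <- function(gs) {
        present <- intersect(gs@genes, rownames(nm))
        if (!length(present))
            stop("no gene of set '", gs@name, "' is present in the matrix")
        ctrl <- unique(unlist(lapply(present, function(g) {
            members <- bin_members[[as.character(bin[[g]])]]
            sample(members, min(nCtrl, length(members)))
        })))
        if (!length(ctrl))
            stop("set '", gs@name, "' exhausts the available control pool")
        Matrix::colMeans(nm[present, , drop = FALSE]) -
            Matrix::colMeans(nm[ctrl, , drop = FALSE])
    }
    scores <- .with_seed(seed, list(S = score_one(sGenes),
                                    G2M = score_one(g2mGenes)))
    phase <- ifelse(pmax(scores$S, scores$G2M) <= 0, "G1",
                    ifelse(scores$S >= scores$G2M, "S", "G2M"))
    data.frame(S_score = scores$S, G2M_score = scores$G2M, phase = phase,
               row.names = colnames(nm))
}

#' Compare per-cell scores across groups (one-way ANOVA + Tukey HSD)
#'
#' For every score column, fits a one-way ANOVA against the grouping and
#' reports the F statistic and p-value plus the all-pairs Tukey honest
#' significant difference table (studentized-range adjusted p-values on the
#' pooled within-group variance).
#'
#' @param scores data.frame or matrix of per-cell scores (cells in rows, one
#'   column per gene set).
#' @param grouping factor-like vector (cluster or tissue label), one entry
#'   per cell; at least two groups with at least two cells each.
#' @return list with `anova` (set, F, p) and `tukey` (set, pair, diff, lwr,
#'   upr, p_adj) data.frames.
#' @export
compareScores <- function(scores, grouping) {
    scores <- as.data.frame(scores)
    g <- factor(grouping)
    if (nlevels(g) < 2) stop("need at least two groups")
    if (any(table(g) < 2)) stop("every group needs at least two cells")
    an <- list(); tk <- list()
    for (set in colnames(scores)) {
        fit <- stats::aov(scores[[set]] ~ g)
        s <- summary(fit)[[1]]
        an[[set]] <- data.frame(set = set, F = s[1, "F value"],
                                p = s[1, "Pr(>F)"])
        th <- stats::TukeyHSD(fit)$g
        tk[[set]] <- data.frame(set = set, pair = rownames(th),
                                diff = th[, "diff"], lwr = th[, "lwr"],
                                upr = th[, "upr"], p_adj = th[, "p adj"],
                                row.names = NULL)
    }
    list(anova = do.call(rbind, c(an, list(make.row.names = FALSE))),
         tukey = do.call(rbind, c(tk, list(make.row.names = FALSE))))
}
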