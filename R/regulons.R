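## Rank-based regulon activity (area under the recovery curve within the
## top-ranked fraction of a cell's genes) and the per-stage transition
## linear model over the cluster graph, with display filtering and
## activation-pattern grouping.

#' Score regulon activity per cell (area under the recovery curve)
#'
#' For each cell, all genes are ranked by expression in decreasing order,
#' ties (notably the zero block) broken by one fixed seeded permutation of
#' gene indices shared across cells. With `k = ceiling(x * n)` genes in the
#' top fraction and recovery curve `c(i)` = number of regulon genes among
#' the top `i`, the activity is `sum_{i=1..k} c(i)` divided by its maximum
#' `sum_{i=1..k} min(i, m)` (`m` = regulon genes present), so activity lies
#' in `[0, 1]` and depends on the expression values only through their
#' within-cell ranks.
#'
#' @param cm a [CellMatrix-class]; the `"logcounts"` assay is used when
#'   present, otherwise raw counts (within-cell ranks are identical).
#' @param regulons list of [Regulon-class]; regulons with no gene in the
#'   matrix are dropped (logged).
#' @param topFraction fraction `x` of top-ranked genes (default 0.05), in
#'   `(0, 1]`.
#' @param seed seed of the shared tie-breaking permutation.
#' @return cells x regulons numeric matrix with entries in `[0, 1]`;
#'   attribute `"topFraction"` records `x`.
#' @export
scoreRegulons <- function(cm, regulons, topFraction = 0.05, seed = 1L) {
    if (!(topFraction > 0 && topFraction <= 1))
        stop("topFraction must be in (0, 1]")
    m <- if ("logcounts" %in% assayNames(cm)) assay(cm, "logcounts")
         else assay(cm, "counts")
    m <- as.matrix(m)
    n <- nrow(m)
    k <- as.integer(ceiling(topFraction * n))
    perm <- .with_seed(seed, sample.int(n))

    ranks <- matrix(0L, n, ncol(m), dimnames = dimnames(m))
    ix <- seq_len(n)
    for (j in seq_len(ncol(m)))
        ranks[order(-m[, j], perm), j] <- ix

    present <- lapply(regulons, function(r) intersect(r@targets, rownames(m)))
    keep <- lengths(present) > 0
    if (!all(keep))
        .log("info", sum(!keep), " regulon(s) with no gene in the matrix dropped")
    regulons <- regulons[keep]; present <- present[keep]
    if (!length(regulons)) stop("no regulon has genes in the matrix")

    act <- matrix(0, ncol(m), length(regulons),
                  dimnames = list(colnames(m),
                                  vapply(regulons, function(r) r@tf, "")))
    for (j in seq_along(regulons)) {
        rk <- ranks[present[[j]], , drop = FALSE]
        mm <- nrow(rk)
        maxraw <- if (mm >= k) k * (k + 1) / 2
                  else mm * (mm + 1) / 2 + (k - mm) * mm
        act[, j] <- colSums(pmax(k - rk + 1L, 0L)) / maxraw
    }
    attr(act, "topFraction") <- topFraction
    act
}

#' Per-stage transition model of regulon activity
#'
#' For each non-root stage `s` with parent `p`, restricts to the cells of
#' `p` and `s` and fits the linear model `activity ~ 1 + I(stage == s)`; the
#' reported t-value is the indicator coefficient over its standard error
#' (algebraically the classical pooled two-sample t-statistic), with a
#' two-sided p-value on `n_p + n_s - 2` degrees of freedom. Each root stage
#' is contrasted against all other cells with the same model, so regulons
#' activated early in the trajectory acquire positive root t-values.
#' P-values are BH-adjusted within each stage column.
#'
#' @param activity cells x regulons matrix from [scoreRegulons()].
#' @param stageLabels per-cell stage (cluster) labels.
#' @param graph a [TransitionGraph-class]; every stage must be present among
#'   the labels with at least two cells.
#' @return A [TransitionTable-class].
#' @export
transitionGlm <- function(activity, stageLabels, graph) {
    stageLabels <- as.character(stageLabels)
    if (length(stageLabels) != nrow(activity))
        stop("one stage label per cell is required")
    missing <- setdiff(graph@stages, stageLabels)
    if (length(missing))
        stop("stage(s) missing from labels: ", paste(missing, collapse = ", "))
    if (any(table(stageLabels)[graph@stages] < 2))
        stop("every stage needs at least two cells")
    parent_of <- stats::setNames(graph@edges$parent, graph@edges$child)

    two_sample_t <- function(a, in1) {
        a1 <- a[in1, , drop = FALSE]
        a0 <- a[!in1, , drop = FALSE]
        n1 <- nrow(a1); n0 <- nrow(a0)
        m1 <- colMeans(a1); m0 <- colMeans(a0)
        ss <- colSums((a1 - rep(m1, each = n1))^2) +
              colSums((a0 - rep(m0, each = n0))^2)
        sp <- sqrt(ss / (n1 + n0 - 2))
        denom <- sp * sqrt(1 / n1 + 1 / n0)
        t <- (m1 - m0) / denom
        t[denom == 0 & (m1 - m0) == 0] <- 0
        p <- 2 * stats::pt(-abs(t), df = n1 + n0 - 2)
        p[t == 0] <- 1
        list(t = t, p = p)
    }

    st <- graph@stages
    tv <- pv <- matrix(NA_real_, ncol(activity), length(st),
                       dimnames = list(colnames(activity), st))
    for (s in st) {
        if (s %in% graph@roots) {
            res <- two_sample_t(activity, stageLabels == s)
        } else {
            sel <- stageLabels %in% c(s, parent_of[[s]])
            res <- two_sample_t(activity[sel, , drop = FALSE],
                                stageLabels[sel] == s)
        }
        tv[, s] <- res$t
        pv[, s] <- res$p
    }
    padj <- pv
    for (s in colnames(padj))
        padj[, s] <- stats::p.adjust(pv[, s], method = "BH")
    methods::new("TransitionTable", tValues = tv, pValues = pv,
                 pAdjusted = padj, graph = graph)
}

#' Regulons passing the display filter
#'
#' @param tt a [TransitionTable-class].
#' @param tDisplay display threshold on `max |t|` over stages (default 20).
#' @return Character vector of regulon names with at least one `|t|`
#'   exceeding `tDisplay`.
#' @export
displayedRegulons <- function(tt, tDisplay = 20) {
    tv <- tt@tValues
    rownames(tv)[apply(abs(tv), 1, max) > tDisplay]
}

#' Group displayed regulons by activation pattern
#'
#' Hierarchically clusters (Ward linkage on Euclidean distances) the rows of
#' the t-value matrix restricted to regulons passing the display filter and
#' cuts the tree into `k` groups. Deterministic; group membership is
#' invariant to regulon order up to label names.
#'
#' @param tt a [TransitionTable-class].
#' @param k number of activation-pattern groups (default 5).
#' @param tDisplay display threshold (default 20); at least `k` regulons
#'   must pass it.
#' @return Named integer vector of group labels for the displayed regulons.
#' @export
groupPatterns <- function(tt, k = 5, tDisplay = 20) {
    shown <- displayedRegulons(tt, tDisplay)
    if (length(shown) < k)
        stop("only ", length(shown), " regulon(s) pass the display filter; ",
             "need at least k = ", k)
    hc <- stats::hclust(stats::dist(tt@tValues[shown, , drop = FALSE]),
                        method = "ward.D2")
    stats::cutree(hc, k = k)
}
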