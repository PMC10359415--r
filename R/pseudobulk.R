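## Pseudobulk construction, median-of-ratios size factors, and
## negative-binomial Wald differential expression (log link, batch-aware,
## method-of-moments dispersion, Benjamini-Hochberg correction).

#' Sum single-cell counts into pseudobulk units
#'
#' Sums UMI counts across all cells sharing the grouping keys: by sample
#' gives in-silico bulk samples, by sample and cluster gives the pseudobulk
#' replicates used for differential expression. Sums are exact integers;
#' total UMI is conserved when `minCells = 0`.
#'
#' @param cm a [CellMatrix-class].
#' @param by per-cell metadata columns to group by; `"sample"` is accepted
#'   as an alias for `"sample_id"`.
#' @param minCells units with fewer contributing cells are dropped with a
#'   warning (default 10).
#' @return A [PseudobulkTable-class] with `sample_id`, optional `cluster`,
#'   `group` (tissue group, when available), `batch` and `n_cells` per unit.
#' @export
makePseudobulk <- function(cm, by = c("sample_id", "cluster"), minCells = 10) {
    by[by == "sample"] <- "sample_id"
    if (!length(by)) stop("empty grouping")
    cd <- as.data.frame(colData(cm))
    missing <- setdiff(by, colnames(cd))
    if (length(missing))
        stop("grouping keys absent from cell metadata: ",
             paste(missing, collapse = ", "))
    key <- do.call(paste, c(cd[by], sep = "."))
    counts <- t(rowsum(as.matrix(Matrix::t(assay(cm, "counts"))), key))
    storage.mode(counts) <- "integer"
    first <- match(colnames(counts), key)
    meta <- data.frame(sample_id = cd$sample_id[first], row.names = colnames(counts))
    if ("cluster" %in% by) meta$cluster <- cd$cluster[first]
    if ("tissue_group" %in% colnames(cd)) meta$group <- cd$tissue_group[first]
    if ("batch" %in% colnames(cd)) meta$batch <- cd$batch[first]
    meta$n_cells <- as.integer(table(key)[colnames(counts)])
    keep <- meta$n_cells >= minCells
    if (!all(keep)) {
        warning(sum(!keep), " pseudobulk unit(s) with fewer than ", minCells,
                " cells dropped: ",
                paste(utils::head(colnames(counts)[!keep], 10), collapse = ", "))
        counts <- counts[, keep, drop = FALSE]
        meta <- meta[keep, , drop = FALSE]
    }
    if (!ncol(counts)) stop("no pseudobulk unit left after filtering")
    methods::new("PseudobulkTable",
                 SummarizedExperiment::SummarizedExperiment(
                     assays = list(counts = counts),
                     colData = DataFrame(meta)))
}

#' Median-of-ratios size factors
#'
#' For each unit, the size factor is the median over all-positive genes of
#' the ratio of the unit's count to the gene's geometric mean across units,
#' rescaled to geometric mean 1. If no gene is positive in every unit, the
#' library-size ratio is used instead (logged).
#'
#' @param pb a [PseudobulkTable-class] with at least two units.
#' @return `pb` with `sizeFactors(pb)` filled.
#' @export
computeSizeFactors <- function(pb) {
    counts <- assay(pb, "counts")
    if (ncol(counts) < 2) stop("size factors need at least two units")
    allpos <- rowSums(counts > 0) == ncol(counts)
    if (any(allpos)) {
        pos <- counts[allpos, , drop = FALSE]
        geo <- exp(rowMeans(log(pos)))
        sf <- apply(pos / geo, 2, stats::median)
    } else {
        .log("warn", "no all-positive gene; falling back to library-size ratios")
        ls <- colSums(counts)
        sf <- ls / exp(mean(log(ls)))
    }
    sf <- sf / exp(mean(log(sf)))
    sizeFactors(pb) <- sf
    pb
}

## one-gene NB GLM with log link, fixed dispersion, log(sf) offset
.nb_irls <- function(y, X, offset, phi, maxIter = 100L, tol = 1e-10) {
    beta <- stats::lm.fit(X, log((y + 0.5) / exp(offset)))$coefficients
    beta[is.na(beta)] <- 0
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        eta <- drop(X %*% beta) + offset
        mu <- pmin(pmax(exp(eta), 1e-10), 1e10)
        w <- mu / (1 + phi * mu)
        z <- (eta - offset) + (y - mu) / mu
        xw <- X * w
        fit <- tryCatch(solve(crossprod(xw, X), crossprod(xw, z)),
                        error = function(e) NULL)
        if (is.null(fit)) break
        delta <- max(abs(fit - beta))
        beta <- drop(fit)
        if (delta < tol) { converged <- TRUE; break }
    }
    eta <- drop(X %*% beta) + offset
    mu <- pmin(pmax(exp(eta), 1e-10), 1e10)
    w <- mu / (1 + phi * mu)
    cov <- tryCatch(solve(crossprod(X * w, X)), error = function(e) NULL)
    list(beta = beta, se = if (is.null(cov)) rep(NA_real_, length(beta))
                           else sqrt(diag(cov)),
         converged = converged && !is.null(cov))
}

#' Negative-binomial Wald differential expression on pseudobulk counts
#'
#' Per gene, fits an NB GLM (log link, variance `mu + phi*mu^2`) of counts
#' on the two-level group factor with optional batch covariate and
#' `log(size factor)` offsets. The dispersion is estimated per gene by
#' method of moments on size-factor-normalized counts,
#' `phi = max((s^2 - mean)/mean^2, 1e-8)` with the moments pooled within
#' the design cells (group x batch levels), then held fixed during IRLS.
#' The Wald statistic is the group coefficient over its standard error; its
#' two-sided p-value is referred to a t distribution on the residual
#' degrees of freedom (normal asymptotics are anticonservative at
#' pseudobulk replicate numbers because the plug-in dispersion is itself
#' estimated from few units). BH adjustment is applied across tested genes.
#' Genes with all-zero counts are excluded (listed in
#' `attr(result, "excluded")`); genes whose IRLS does not converge within
#' `maxIter` iterations are flagged with `p = NA`.
#'
#' @param pb a [PseudobulkTable-class] with size factors (see
#'   [computeSizeFactors()]); at least two units per group level.
#' @param group name of the colData column holding the two-level group, or a
#'   vector of labels per unit.
#' @param batch optional colData column name (or vector) of batch labels.
#' @param ref reference group level; the log2 fold change is toward the
#'   other level.
#' @param dispersion optional fixed dispersion (scalar or per-gene vector)
#'   overriding the method-of-moments estimate.
#' @param maxIter IRLS iteration cap (default 100).
#' @return data.frame with columns `gene`, `base_mean`, `log2_fc`, `se`,
#'   `stat`, `pvalue`, `padj`, `converged`.
#' @export
nbWaldDE <- function(pb, group = "group", batch = NULL, ref = NULL,
                     dispersion = NULL, maxIter = 100L) {
    counts <- assay(pb, "counts")
    sf <- sizeFactors(pb)
    if (is.null(sf)) stop("size factors missing; run computeSizeFactors()")
    g <- if (length(group) == 1L) colData(pb)[[group]] else group
    g <- factor(g)
    if (!is.null(ref)) g <- stats::relevel(g, ref)
    if (nlevels(g) != 2) stop("group must have exactly two levels")
    if (any(table(g) < 2)) stop("need at least two units per group level")
    b <- if (is.null(batch)) NULL
         else if (length(batch) == 1L) factor(colData(pb)[[batch]])
         else factor(batch)
    X <- if (is.null(b) || nlevels(b) < 2) stats::model.matrix(~g)
         else stats::model.matrix(~ b + g)
    gcol <- ncol(X)
    rdf <- ncol(counts) - ncol(X)   # residual df for the Wald reference
    if (rdf < 1) stop("design leaves no residual degrees of freedom")
    offset <- log(sf)

    nonzero <- rowSums(counts) > 0
    excluded <- rownames(counts)[!nonzero]
    genes <- rownames(counts)[nonzero]
    q <- sweep(counts[nonzero, , drop = FALSE], 2, sf, "/")
    mu_bar <- rowMeans(q)
    ## method-of-moments dispersion on normalized counts, with moments
    ## pooled within the design cells (group x batch levels) so that true
    ## effects do not inflate the dispersion
    cell <- if (is.null(b)) g else interaction(g, b, drop = TRUE)
    num <- den <- numeric(length(genes))
    for (lev in levels(cell)) {
        j <- cell == lev
        nj <- sum(j)
        if (nj < 2) next
        mj <- rowMeans(q[, j, drop = FALSE])
        s2j <- rowSums((q[, j, drop = FALSE] - mj)^2) / (nj - 1)
        num <- num + (nj - 1) * (s2j - mj)
        den <- den + (nj - 1) * mj^2
    }
    phi <- pmax(num / pmax(den, .Machine$double.eps), 1e-8)
    if (!is.null(dispersion))
        phi <- rep_len(dispersion, length(genes))

    res <- matrix(NA_real_, length(genes), 4,
                  dimnames = list(genes, c("beta", "se", "stat", "p")))
    conv <- logical(length(genes))
    cts <- counts[nonzero, , drop = FALSE]
    for (i in seq_along(genes)) {
        fit <- .nb_irls(cts[i, ], X, offset, phi[i], maxIter = maxIter)
        conv[i] <- fit$converged
        if (fit$converged) {
            res[i, ] <- c(fit$beta[gcol], fit$se[gcol],
                          fit$beta[gcol] / fit$se[gcol], NA)
            res[i, "p"] <- 2 * stats::pt(-abs(res[i, "stat"]), df = rdf)
        }
    }
    if (!all(conv))
        .log("warn", sum(!conv), " gene(s) did not converge; p set to NA")
    out <- data.frame(gene = genes,
                      base_mean = mu_bar,
                      log2_fc = res[, "beta"] / log(2),
                      se = res[, "se"] / log(2),
                      stat = res[, "stat"],
                      pvalue = res[, "p"],
                      padj = stats::p.adjust(res[, "p"], "BH"),
                      converged = conv,
                      row.names = NULL)
    attr(out, "excluded") <- excluded
    attr(out, "contrast") <- paste(levels(g)[2], "vs", levels(g)[1])
    out
}
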