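## Dual-omics transcription factor candidate screen: intersect TFs whose
## expression tracks the upregulated non-TF program in both modalities with
## TFs whose regulon is strongly activated in the early (non-senescent)
## stages, then extract a candidate's positively correlated,
## dual-omics-upregulated non-TF module.

#' Configuration of the TF candidate screen
#'
#' @param cor_threshold minimum Pearson correlation of a TF with the
#'   upregulated-gene profile (default 0.9).
#' @param cor_p p-value cut for that correlation (one-sided positive
#'   association, default 0.05).
#' @param module_cor minimum TF-gene correlation for module membership
#'   (default 0.8).
#' @param module_p_adj BH-adjusted p cut for module correlations
#'   (default 0.05).
#' @param regulon_t minimum transition t-value in an early stage
#'   (default 30).
#' @param regulon_p p-value cut for the regulon arm (default 0.05).
#' @param early_stages stage labels counted as early/non-senescent.
#' @param tf_list transcription factor universe (gene ids).
#' @param per_gene if `TRUE`, the correlation arm tests each upregulated
#'   gene separately and requires a qualifying fraction, instead of the
#'   default aggregate mean-profile correlation.
#' @param qualifying_fraction fraction of upregulated genes that must pass
#'   in per-gene mode (default 0.5).
#' @return list of class `"TFScreenConfig"`.
#' @export
tfScreenConfig <- function(cor_threshold = 0.9, cor_p = 0.05,
                           module_cor = 0.8, module_p_adj = 0.05,
                           regulon_t = 30, regulon_p = 0.05,
                           early_stages = c("C1", "C2", "C3"),
                           tf_list = character(0),
                           per_gene = FALSE, qualifying_fraction = 0.5) {
    for (v in c(cor_threshold, module_cor))
        if (!(v > 0 && v < 1)) stop("correlation thresholds must be in (0, 1)")
    if (regulon_t <= 0) stop("regulon_t must be positive")
    structure(list(cor_threshold = cor_threshold, cor_p = cor_p,
                   module_cor = module_cor, module_p_adj = module_p_adj,
                   regulon_t = regulon_t, regulon_p = regulon_p,
                   early_stages = early_stages, tf_list = tf_list,
                   per_gene = per_gene,
                   qualifying_fraction = qualifying_fraction),
              class = "TFScreenConfig")
}

## Pearson r and one-sided (positive association) p on n-2 df
.cor_pos <- function(u, v) {
    r <- stats::cor(u, v)
    n <- length(u)
    t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    c(r = r, p = stats::pt(t, df = n - 2, lower.tail = FALSE))
}

#' Correlation arm of the TF screen
#'
#' For each TF of the configured universe present in the transcript matrix,
#' correlates its expression across samples with the mean profile of the
#' upregulated non-TF genes, separately per modality (the protein side uses
#' the TF's protein row when present; otherwise the TF is evaluated on RNA
#' only and flagged). A TF passes when `r > cor_threshold` with one-sided
#' `p < cor_p` in every evaluated modality.
#'
#' @param rna genes x samples log-scale transcript matrix (at least 4
#'   samples).
#' @param protein genes x samples log-scale protein matrix (rownames are
#'   gene ids).
#' @param upGenes non-TF genes upregulated in the target group in both
#'   omics (e.g. from [nbWaldDE()]); non-empty.
#' @param cfg a [tfScreenConfig()].
#' @return data.frame: `tf`, `r_rna`, `p_rna`, `r_protein`, `p_protein`,
#'   `protein_evaluated`, `pass`.
#' @export
correlatedTfs <- function(rna, protein, upGenes, cfg) {
    if (ncol(rna) < 4 || ncol(protein) < 4)
        stop("need at least 4 samples per modality")
    if (!length(upGenes)) stop("upGenes must be non-empty")
    tfs <- intersect(cfg$tf_list, rownames(rna))

    eval_modality <- function(m, tfid) {
        up <- intersect(upGenes, rownames(m))
        if (!length(up) || !tfid %in% rownames(m))
            return(NULL)
        v <- m[tfid, ]
        if (cfg$per_gene) {
            res <- vapply(up, function(g) .cor_pos(v, m[g, ]), c(r = 0, p = 0))
            frac <- mean(res["r", ] > cfg$cor_threshold &
                         res["p", ] < cfg$cor_p)
            c(r = mean(res["r", ]), p = NA,
              pass = frac >= cfg$qualifying_fraction)
        } else {
            profile <- colMeans(m[up, , drop = FALSE])
            rp <- .cor_pos(v, profile)
            c(rp, pass = unname(rp["r"] > cfg$cor_threshold &
                                rp["p"] < cfg$cor_p))
        }
    }
    rows <- lapply(tfs, function(tfid) {
        rr <- eval_modality(rna, tfid)
        pp <- eval_modality(protein, tfid)
        data.frame(tf = tfid,
                   r_rna = rr[["r"]], p_rna = rr[["p"]],
                   r_protein = if (is.null(pp)) NA_real_ else pp[["r"]],
                   p_protein = if (is.null(pp)) NA_real_ else pp[["p"]],
                   protein_evaluated = !is.null(pp),
                   pass = rr[["pass"]] == 1 &&
                       (is.null(pp) || pp[["pass"]] == 1))
    })
    do.call(rbind, rows)
}

#' Intersect the two screen arms into the candidate set
#'
#' Candidates are TFs passing the correlation arm whose regulon has
#' `t > regulon_t` with `p < regulon_p` in at least one early stage of the
#' transition table.
#'
#' @param correlated result of [correlatedTfs()] (or a character vector of
#'   passing TFs).
#' @param tt a [TransitionTable-class] whose rows share the TF vocabulary.
#' @param cfg a [tfScreenConfig()]; `early_stages` must be non-empty.
#' @return list with `candidates`, `correlation_arm`, `regulon_arm` and an
#'   `evidence` data.frame (per candidate: correlations and max early-stage
#'   t).
#' @export
screenTfs <- function(correlated, tt, cfg) {
    if (!length(cfg$early_stages)) stop("early_stages must be non-empty")
    corr_pass <- if (is.data.frame(correlated))
        correlated$tf[correlated$pass] else as.character(correlated)
    st <- intersect(cfg$early_stages, colnames(tt@tValues))
    if (!length(st)) stop("no early stage present in the transition table")
    tv <- tt@tValues[, st, drop = FALSE]
    pv <- tt@pValues[, st, drop = FALSE]
    hit <- rowSums(tv > cfg$regulon_t & pv < cfg$regulon_p) > 0
    reg_pass <- rownames(tv)[hit]
    cand <- intersect(corr_pass, reg_pass)
    evidence <- data.frame(
        tf = cand,
        max_t_early = apply(tv[cand, , drop = FALSE], 1, max),
        row.names = NULL)
    if (is.data.frame(correlated))
        evidence <- merge(evidence,
                          correlated[correlated$tf %in% cand,
                                     c("tf", "r_rna", "r_protein")],
                          by = "tf", sort = TRUE)
    list(candidates = sort(cand), correlation_arm = sort(corr_pass),
         regulon_arm = sort(reg_pass), evidence = evidence)
}

#' Extract a TF's positively correlated, dual-omics-upregulated module
#'
#' Screens non-TF genes whose transcript profile is strongly positively
#' correlated with the TF across samples (`r > module_cor`, BH-adjusted
#' one-sided `p < module_p_adj` over all tested non-TF genes) and that are
#' upregulated toward the target group in both the transcript and protein
#' differential expression results (`padj < dePadj`, positive log2 fold
#' change).
#'
#' @param tfId the TF gene id (must be present in `rna`).
#' @param rna genes x samples log-scale transcript matrix.
#' @param deRna,deProtein [nbWaldDE()] results oriented so that positive
#'   `log2_fc` points toward the target group.
#' @param cfg a [tfScreenConfig()].
#' @param dePadj adjusted-p cut applied to both DE tables (default 0.05).
#' @return data.frame of tested genes: `gene`, `r`, `p`, `padj`,
#'   `up_rna`, `up_protein`, `in_module`.
#' @export
tfModule <- function(tfId, rna, deRna, deProtein, cfg, dePadj = 0.05) {
    if (!tfId %in% rownames(rna)) stop("TF '", tfId, "' absent from rna matrix")
    genes <- setdiff(rownames(rna), union(cfg$tf_list, tfId))
    v <- rna[tfId, ]
    res <- vapply(genes, function(g) .cor_pos(v, rna[g, ]), c(r = 0, p = 0))
    padj <- stats::p.adjust(res["p", ], "BH")
    up_in <- function(de, g) {
        i <- match(g, de$gene)
        !is.na(i) & !is.na(de$padj[i]) & de$padj[i] < dePadj & de$log2_fc[i] > 0
    }
    up_rna <- up_in(deRna, genes)
    up_prot <- up_in(deProtein, genes)
    data.frame(gene = genes, r = res["r", ], p = res["p", ], padj = padj,
               up_rna = up_rna, up_protein = up_prot,
               in_module = res["r", ] > cfg$module_cor &
                   padj < cfg$module_p_adj & up_rna & up_prot,
               row.names = NULL)
}
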