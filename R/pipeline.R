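## End-to-end driver: runs the full analysis on a simulated dataset with
## planted truth -- normalization, regulon activity, transition models,
## dual-omics differential expression, integration and the TF screen.

#' Negative-binomial Wald differential expression on a proteome table
#'
#' Rounds intensities to integer counts (count-based DE on peak areas, as
#' is common practice for label-free quantification) and applies
#' [nbWaldDE()] with median-of-ratios size factors. Proteins with a
#' duplicated gene mapping are dropped.
#'
#' @param pt a [ProteomeTable-class].
#' @param ref reference group level; log2 fold change is toward the other
#'   level.
#' @return A [nbWaldDE()] result indexed by gene id.
#' @export
proteinWaldDE <- function(pt, ref = NULL) {
    counts <- round(assay(pt, "intensity"))
    storage.mode(counts) <- "integer"
    gene <- as.character(rowData(pt)$gene_id)
    keep <- !duplicated(gene)
    counts <- counts[keep, , drop = FALSE]
    rownames(counts) <- gene[keep]
    pb <- methods::new("PseudobulkTable",
                       SummarizedExperiment::SummarizedExperiment(
                           assays = list(counts = counts),
                           colData = DataFrame(
                               sample_id = colnames(counts),
                               group = colData(pt)$group,
                               row.names = colnames(counts))))
    pb <- computeSizeFactors(pb)
    nbWaldDE(pb, group = "group", ref = ref)
}

#' Run the full analysis on a simulated dataset
#'
#' Executes the pipeline end to end on the output of [simulateMsc()]:
#' depth normalization, regulon activity scoring, the per-stage transition
#' models, sample-level in-silico bulk with NB Wald differential expression
#' in both omics (batch-aware on the transcript side), the dual-omics
#' upregulated gene set, the omics merge with PCA, and the TF candidate
#' screen with module extraction for the planted master TF.
#'
#' @param sim result of [simulateMsc()].
#' @param targetGroup tissue group treated as the screen's target
#'   (default `"perinatal"`); the other level is the DE reference.
#' @param seed seed for the rank tie-break permutation and control draws.
#' @param screenConfig optional [tfScreenConfig()]; defaults to the paper
#'   thresholds with `early_stages` set to the trajectory's root stages and
#'   the simulation's TF universe.
#' @return list with `activity`, `transitions`, `de_rna`, `de_protein`,
#'   `up_genes`, `omics`, `pca`, `screen`, `module` and the matrices
#'   `rna`/`protein` used by the screen.
#' @export
analyzeSimulation <- function(sim, targetGroup = "perinatal", seed = 1L,
                              screenConfig = NULL) {
    cm <- normalizeCells(sim$cells)
    act <- scoreRegulons(cm, sim$regulons, seed = seed)
    cd <- colData(cm)
    stage <- if ("stage" %in% colnames(cd)) cd$stage else cd$cluster
    tt <- transitionGlm(act, stage, sim$graph)

    pbs <- computeSizeFactors(makePseudobulk(sim$cells, by = "sample",
                                             minCells = 0))
    groups <- unique(as.character(colData(pbs)$group))
    ref <- setdiff(groups, targetGroup)
    if (length(ref) != 1) stop("targetGroup must leave one reference level")
    de_rna <- nbWaldDE(pbs, group = "group", batch = "batch", ref = ref)
    de_prot <- proteinWaldDE(sim$proteome, ref = ref)

    tf_ids <- sim$truth$tf_ids
    up <- setdiff(
        intersect(de_rna$gene[de_rna$padj < 0.05 & de_rna$log2_fc > 0],
                  de_prot$gene[de_prot$padj < 0.05 & de_prot$log2_fc > 0]),
        tf_ids)

    rna <- logCpm(pbs)
    prot <- log2(assay(sim$proteome, "intensity") + 1)
    rownames(prot) <- rowData(sim$proteome)$gene_id

    cfg <- if (is.null(screenConfig))
        tfScreenConfig(early_stages = rootStages(sim$graph),
                       tf_list = tf_ids)
    else screenConfig

    corr <- if (length(up)) correlatedTfs(rna, prot, up, cfg) else NULL
    scr <- if (is.null(corr)) list(candidates = character(0))
           else screenTfs(corr, tt, cfg)
    mod <- tfModule(sim$truth$master_tf, rna, de_rna, de_prot, cfg)

    op <- mergeOmics(pbs, sim$proteome)
    list(activity = act, transitions = tt, pseudobulk = pbs,
         de_rna = de_rna, de_protein = de_prot, up_genes = up,
         rna = rna, protein = prot, omics = op, pca = mergedPca(op),
         correlations = corr, screen = scr, module = mod,
         screen_config = cfg)
}
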