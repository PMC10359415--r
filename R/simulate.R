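## Synthetic-data generator. Plants known ground truth -- cluster-specific
## gene programs on a branching senescence trajectory, regulon-driven
## co-expression with one master TF, tissue-group composition differences,
## planted group-DE genes, and a matched bulk proteome -- so that every
## downstream stage of the pipeline is testable without external downloads.

#' Simulation configuration
#'
#' Returns a validated configuration for [simulateMsc()]. Defaults emulate
#' the study design the pipeline targets: seven clusters `C1..C7` on a
#' branching senescence trajectory (`C1->C2->C3->C4 -> {C5,C6,C7}`), six
#' perinatal and six adult samples in three batches with differing
#' senescent-cluster proportions, negative-binomial UMI counts
#' (variance = mu + phi*mu^2), and a matched proteome whose log2 intensity
#' tracks in-silico-bulk log-CPM with noise.
#'
#' @param n_genes total genes, including `n_tfs` transcription factor genes.
#' @param n_tfs number of TF genes (ids `TF01`, `TF02`, ...).
#' @param clusters named list: per cluster, a named numeric vector of program
#'   weights over `proliferation`, `senescence`, `UPR`, `immunosuppression`.
#' @param master_activation named numeric: per-cluster activation level of
#'   the master TF's regulon (high in root stages, zero in senescent leaves).
#' @param samples data.frame with columns `sample_id`, `tissue_group`,
#'   `batch`, `n_cells`, plus one `prop_<cluster>` column per cluster
#'   (proportions sum to 1 per sample).
#' @param n_cells cells per sample used when `samples` is left at its
#'   default (default 500).
#' @param edges transition-graph edge list (`parent`, `child`; `"ROOT"`
#'   allowed). The default pools the proliferative clusters into one root
#'   stage `C123` followed by the transition state `C4` and three
#'   independent senescent leaves `C5`, `C6`, `C7`.
#' @param stage_map named character vector mapping cluster labels onto the
#'   graph's stage labels (default: identity, except `C1`,`C2`,`C3` map to
#'   `C123` when that stage exists).
#' @param nb_dispersion NB dispersion phi (> 0).
#' @param libsize_meanlog,libsize_sdlog log-normal library-size parameters.
#' @param regulon_size targets per regulon.
#' @param master_tf_effect log-scale activation of a regulon's targets in
#'   its fully activated clusters (shared by all pattern regulons).
#' @param master_tf_group_log2fc planted log2 upregulation of the master TF
#'   gene itself in the perinatal group (the master regulator is itself
#'   group-differential, beyond the composition effect).
#' @param regulon_activation optional TFs x clusters activation matrix; the
#'   default plants one early-activated master regulon, four regulons
#'   specific to each of the transition state and the three senescent
#'   leaves (the five activation-pattern archetypes), and leaves the
#'   remaining regulons without stage dynamics.
#' @param program_effect log-scale effect of a unit program weight.
#' @param program_size genes per program.
#' @param n_de planted group-DE genes per direction (perinatal-up, adult-up).
#' @param de_log2fc planted log2 fold change of group-DE genes.
#' @param batch_sd log-scale sd of per-batch gene offsets.
#' @param latent_sd sd of the per-cell latent regulon activity noise.
#' @param proteome_noise_sd sd (log2 scale) of proteome measurement noise.
#' @param modality_offset_sd sd of the per-gene protein-vs-RNA offset.
#' @param proteome_coverage number of genes detected in the proteome.
#' @param seed integer RNG seed; the simulation is deterministic given the
#'   full configuration.
#' @return A list of class `"SimConfig"`.
#' @export
simConfig <- function(n_genes = 2000L,
                      n_tfs = 40L,
                      clusters = NULL,
                      master_activation = NULL,
                      samples = NULL,
                      n_cells = 500L,
                      edges = NULL,
                      stage_map = NULL,
                      nb_dispersion = 0.3,
                      libsize_meanlog = log(5000),
                      libsize_sdlog = 0.3,
                      regulon_size = 30L,
                      master_tf_effect = 1.0,
                      master_tf_group_log2fc = 1.5,
                      regulon_activation = NULL,
                      program_effect = 1.0,
                      program_size = 100L,
                      n_de = 80L,
                      de_log2fc = 1.0,
                      batch_sd = 0.1,
                      latent_sd = 0.3,
                      proteome_noise_sd = 0.4,
                      modality_offset_sd = 2.0,
                      proteome_coverage = 1400L,
                      seed = 1L) {
    if (is.null(clusters)) {
        clusters <- list(
            C1 = c(proliferation = 1.0, senescence = 0.0, UPR = 0.0, immunosuppression = 1.0),
            C2 = c(proliferation = 1.0, senescence = 0.0, UPR = 0.0, immunosuppression = 1.0),
            C3 = c(proliferation = 0.8, senescence = 0.0, UPR = 0.0, immunosuppression = 0.9),
            C4 = c(proliferation = 0.4, senescence = 0.3, UPR = 0.0, immunosuppression = 0.5),
            C5 = c(proliferation = 0.0, senescence = 1.0, UPR = 1.0, immunosuppression = 0.1),
            C6 = c(proliferation = 0.0, senescence = 1.1, UPR = 0.0, immunosuppression = 0.0),
            C7 = c(proliferation = 0.0, senescence = 1.2, UPR = 0.0, immunosuppression = 0.0))
    }
    cl_names <- names(clusters)
    if (is.null(master_activation)) {
        master_activation <- stats::setNames(rep(0, length(cl_names)), cl_names)
        master_activation[intersect(c("C1", "C2", "C3"), cl_names)] <- 1
        master_activation[intersect("C4", cl_names)] <- 0.5
    }
    if (is.null(samples)) {
        peri <- c(C1 = .24, C2 = .24, C3 = .22, C4 = .12, C5 = .07, C6 = .05, C7 = .06)
        adul <- c(C1 = .06, C2 = .05, C3 = .04, C4 = .15, C5 = .15, C6 = .15, C7 = .40)
        mk <- function(ids, grp, props) {
            df <- data.frame(sample_id = ids, tissue_group = grp,
                             batch = rep(c("b1", "b2", "b3"), each = 2),
                             n_cells = as.integer(n_cells))
            for (cl in names(props)) df[[paste0("prop_", cl)]] <- props[[cl]]
            df
        }
        samples <- rbind(mk(paste0("P", 1:6), "perinatal", peri),
                         mk(paste0("A", 1:6), "adult", adul))
    }
    if (is.null(edges)) {
        ## branching trajectory: pooled proliferative root C123, transition
        ## state C4, three independent senescent leaves
        edges <- data.frame(
            parent = c("ROOT", "C123", "C4", "C4", "C4"),
            child  = c("C123", "C4", "C5", "C6", "C7"))
    }
    if (is.null(stage_map)) {
        graph_stages <- unique(c(edges$child,
                                 edges$parent[edges$parent != "ROOT"]))
        stage_map <- stats::setNames(names(clusters), names(clusters))
        if ("C123" %in% graph_stages)
            stage_map[intersect(c("C1", "C2", "C3"), names(clusters))] <- "C123"
    }
    cl_names <- names(clusters)
    if (is.null(regulon_activation)) {
        ## regulon activation archetypes: the master TF is activated early;
        ## four blocks of decoy regulons are specific to the transition state
        ## or one senescent leaf (the five activation-pattern groups); the
        ## remaining regulons carry co-expression but no stage dynamics
        regulon_activation <- matrix(
            0, n_tfs, length(cl_names),
            dimnames = list(sprintf("TF%02d", seq_len(n_tfs)), cl_names))
        regulon_activation[1, ] <- master_activation[cl_names]
        block <- 2L
        for (cl in intersect(c("C4", "C5", "C6", "C7"), cl_names)) {
            rows <- seq(block, length.out = 4)
            rows <- rows[rows <= n_tfs]
            regulon_activation[rows, cl] <- 1
            block <- block + 4L
        }
    }
    cfg <- structure(list(
        n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
        clusters = clusters, master_activation = master_activation,
        samples = samples, edges = edges, stage_map = stage_map,
        nb_dispersion = nb_dispersion,
        libsize_meanlog = libsize_meanlog, libsize_sdlog = libsize_sdlog,
        regulon_size = as.integer(regulon_size),
        master_tf_effect = master_tf_effect,
        master_tf_group_log2fc = master_tf_group_log2fc,
        regulon_activation = regulon_activation,
        program_effect = program_effect,
        program_size = as.integer(program_size),
        n_de = as.integer(n_de), de_log2fc = de_log2fc,
        batch_sd = batch_sd, latent_sd = latent_sd,
        proteome_noise_sd = proteome_noise_sd,
        modality_offset_sd = modality_offset_sd,
        proteome_coverage = as.integer(proteome_coverage),
        seed = as.integer(seed)), class = "SimConfig")
    .validateSimConfig(cfg)
    cfg
}

.validateSimConfig <- function(cfg) {
    if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
    for (v in c("n_genes", "n_tfs", "regulon_size", "program_size"))
        if (cfg[[v]] <= 0) stop(v, " must be positive")
    cl <- names(cfg$clusters)
    prop_cols <- paste0("prop_", cl)
    if (!all(prop_cols %in% colnames(cfg$samples)))
        stop("samples must have one prop_<cluster> column per cluster")
    ps <- rowSums(cfg$samples[, prop_cols, drop = FALSE])
    if (any(abs(ps - 1) > 1e-6))
        stop("cluster proportions must sum to 1 for every sample")
    need <- 4L * cfg$program_size + 2L * cfg$n_de + cfg$regulon_size
    if (cfg$n_genes - cfg$n_tfs < need)
        stop("not enough non-TF genes for programs, DE genes and the master regulon")
    if (!all(names(cfg$master_activation) == cl))
        stop("master_activation must be named by cluster")
    if (!all(cl %in% names(cfg$stage_map)))
        stop("stage_map must cover every cluster")
    if (!identical(dim(cfg$regulon_activation),
                   c(as.integer(cfg$n_tfs), length(cl))))
        stop("regulon_activation must be an n_tfs x n_clusters matrix")
    graph_stages <- unique(c(cfg$edges$child,
                             cfg$edges$parent[cfg$edges$parent != "ROOT"]))
    if (!all(cfg$stage_map[cl] %in% graph_stages))
        stop("stage_map must map clusters onto the graph's stages")
    invisible(TRUE)
}

## deterministic largest-remainder apportionment of n cells to proportions
.apportion <- function(n, props) {
    raw <- n * props
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1L
    }
    as.integer(base)
}

#' Simulate a single-cell dataset with matched proteome and planted truth
#'
#' Counts are drawn per cell from NB(mu = libsize * p, dispersion phi) where
#' p is the softmax over genes of baseline log-rates plus cluster program
#' effects, tissue-group DE effects, batch offsets and per-cell latent
#' regulon activities. The master TF's regulon carries a cluster-dependent
#' activation (high at the trajectory root, zero in senescent leaves);
#' decoy regulons carry cell-level co-expression but no stage dynamics.
#' The proteome's log2 intensity is `log2(in-silico-bulk CPM + 1)` plus a
#' per-gene modality offset and Gaussian noise.
#'
#' @param config a [simConfig()] object.
#' @return A list with elements `cells` ([CellMatrix-class]), `proteome`
#'   ([ProteomeTable-class]), `regulons` (named list of
#'   [Regulon-class]), `graph` ([TransitionGraph-class]) and `truth`
#'   (ground-truth list: program gene lists, regulon memberships,
#'   `master_tf`, S/G2M marker lists, planted DE genes per direction,
#'   per-cluster expected expression proportions, stage order).
#' @export
simulateMsc <- function(config = simConfig()) {
    stopifnot(inherits(config, "SimConfig"))
    .validateSimConfig(config)
    set.seed(config$seed)
    n_tf <- config$n_tfs
    n_other <- config$n_genes - n_tf
    tf_ids <- sprintf("TF%02d", seq_len(n_tf))
    other_ids <- sprintf("G%04d", seq_len(n_other))
    gene_ids <- c(tf_ids, other_ids)

    baseline <- stats::rnorm(config$n_genes, 0, 1)
    names(baseline) <- gene_ids

    ## carve disjoint planted gene pools out of the non-TF genes
    pool <- other_ids
    take <- function(n) {
        picked <- sample(pool, n)
        pool <<- setdiff(pool, picked)
        picked
    }
    programs <- list(proliferation = take(config$program_size),
                     senescence = take(config$program_size),
                     UPR = take(config$program_size),
                     immunosuppression = take(config$program_size))
    de_up_perinatal <- take(config$n_de)
    de_up_adult <- take(config$n_de)
    master_tf <- tf_ids[1]
    master_targets <- take(config$regulon_size)
    ## decoy regulons draw from the stage-neutral remainder (overlap allowed)
    regulons <- c(stats::setNames(list(Regulon(master_tf, master_targets)), master_tf),
                  stats::setNames(lapply(tf_ids[-1], function(tfid)
                      Regulon(tfid, sample(pool, config$regulon_size))),
                      tf_ids[-1]))

    cl_names <- names(config$clusters)
    programs_m <- matrix(0, config$n_genes, length(cl_names),
                         dimnames = list(gene_ids, cl_names))
    for (cl in cl_names) {
        w <- config$clusters[[cl]]
        for (p in names(w))
            programs_m[programs[[p]], cl] <-
                programs_m[programs[[p]], cl] + w[[p]] * config$program_effect
    }

    batches <- unique(config$samples$batch)
    batch_off <- matrix(stats::rnorm(config$n_genes * length(batches), 0,
                                     config$batch_sd),
                        config$n_genes, length(batches),
                        dimnames = list(gene_ids, batches))

    group_eff <- matrix(0, config$n_genes, 2,
                        dimnames = list(gene_ids, c("perinatal", "adult")))
    group_eff[de_up_perinatal, "perinatal"] <- config$de_log2fc * log(2)
    group_eff[de_up_adult, "adult"] <- config$de_log2fc * log(2)
    ## the master regulator itself is upregulated in the perinatal group
    ## beyond the composition effect
    if ("perinatal" %in% config$samples$tissue_group)
        group_eff[master_tf, "perinatal"] <-
            config$master_tf_group_log2fc * log(2)

    ## per-cell bookkeeping
    smp <- config$samples
    cell_sample <- cell_cluster <- character(0)
    for (i in seq_len(nrow(smp))) {
        nc <- .apportion(smp$n_cells[i],
                         as.numeric(smp[i, paste0("prop_", cl_names)]))
        cell_sample <- c(cell_sample, rep(smp$sample_id[i], sum(nc)))
        cell_cluster <- c(cell_cluster, rep(cl_names, nc))
    }
    n_cells <- length(cell_sample)
    cell_ids <- sprintf("%s_c%04d", cell_sample,
                        stats::ave(seq_len(n_cells), cell_sample,
                                   FUN = seq_along))
    meta_ix <- match(cell_sample, smp$sample_id)
    cell_group <- smp$tissue_group[meta_ix]
    cell_batch <- smp$batch[meta_ix]

    ## genes x cells log-rate
    lograte <- matrix(baseline, config$n_genes, n_cells)
    rownames(lograte) <- gene_ids
    lograte <- lograte + programs_m[, cell_cluster] +
        batch_off[, cell_batch] + group_eff[, cell_group]

    ## latent per-cell regulon activities: every regulon has cell-level
    ## co-expression noise; regulons with a planted activation archetype
    ## additionally follow their per-cluster activation level
    A <- config$regulon_activation
    for (tfid in tf_ids) {
        a <- config$master_tf_effect * A[tfid, cell_cluster] +
            stats::rnorm(n_cells, 0, config$latent_sd)
        rows <- c(tfid, regulons[[tfid]]@targets)
        lograte[rows, ] <- lograte[rows, ] + rep(a, each = length(rows))
    }

    libsize <- stats::rlnorm(n_cells, config$libsize_meanlog,
                             config$libsize_sdlog)
    p <- exp(lograte)
    p <- sweep(p, 2, colSums(p), "/")
    mu <- sweep(p, 2, libsize, "*")
    counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / config$nb_dispersion),
                     nrow = config$n_genes,
                     dimnames = list(gene_ids, cell_ids))

    cm <- CellMatrix(counts,
                     data.frame(sample_id = cell_sample,
                                tissue_group = cell_group,
                                batch = cell_batch,
                                cluster = cell_cluster,
                                stage = unname(config$stage_map[cell_cluster]),
                                row.names = cell_ids))

    ## matched proteome: log2(in-silico-bulk CPM + 1) + offset + noise
    bulk <- t(rowsum(t(counts), cell_sample))  # genes x samples
    bulk <- bulk[, smp$sample_id, drop = FALSE]
    cpm <- sweep(bulk, 2, colSums(bulk), "/") * 1e6
    covered <- sort(sample(gene_ids, min(config$proteome_coverage,
                                         config$n_genes)))
    offset <- stats::rnorm(length(covered), 0, config$modality_offset_sd)
    l2 <- log2(cpm[covered, , drop = FALSE] + 1) + offset +
        matrix(stats::rnorm(length(covered) * ncol(bulk), 0,
                            config$proteome_noise_sd),
               length(covered))
    intens <- 2^l2
    rownames(intens) <- paste0(covered, "_prot")
    proteome <- ProteomeTable(intens, covered,
                              data.frame(group = smp$tissue_group,
                                         batch = smp$batch,
                                         row.names = smp$sample_id))

    graph <- TransitionGraph(config$edges)
    ## expected within-cluster expression proportions (reference batch/group)
    eff <- programs_m
    for (tfid in tf_ids) {
        rows <- c(tfid, regulons[[tfid]]@targets)
        eff[rows, ] <- eff[rows, ] + config$master_tf_effect *
            matrix(A[tfid, ], length(rows), length(cl_names), byrow = TRUE)
    }
    expected <- exp(baseline + eff)
    expected <- sweep(expected, 2, colSums(expected), "/")
    dimnames(expected) <- list(gene_ids, cl_names)

    truth <- list(programs = programs,
                  regulons = lapply(regulons, function(r) r@targets),
                  master_tf = master_tf,
                  s_genes = programs$proliferation[
                      seq_len(min(30, config$program_size %/% 2))],
                  g2m_genes = programs$proliferation[
                      min(30, config$program_size %/% 2) +
                      seq_len(min(30, config$program_size -
                                      config$program_size %/% 2))],
                  de_up_perinatal = de_up_perinatal,
                  de_up_adult = de_up_adult,
                  cluster_means = expected,
                  master_activation = config$master_activation,
                  regulon_activation = A,
                  stage_map = config$stage_map,
                  stage_order = graph@stages,
                  early_stage = graph@roots,
                  tf_ids = tf_ids)

    list(cells = cm, proteome = proteome, regulons = regulons,
         graph = graph, truth = truth)
}

#' Write a simulation to disk in the pipeline's on-disk formats
#'
#' Writes the count matrix (MatrixMarket triple + `meta.csv`), the proteome
#' (`proteome.csv` + `proteome_meta.csv`), `regulons.gmt`, program gene sets
#' (`sets.gmt`), cell-cycle marker sets (`s_genes.gmt`, `g2m_genes.gmt`),
#' the transition graph (`graph.tsv`), the TF universe (`tfs.txt`) and
#' `ground_truth.json`.
#'
#' @param sim result of [simulateMsc()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCellMatrix(sim$cells, file.path(dir, "counts"))
    writeProteomeTable(sim$proteome, file.path(dir, "proteome.csv"),
                       file.path(dir, "proteome_meta.csv"))
    writeGmt(sim$regulons, file.path(dir, "regulons.gmt"))
    writeGmt(lapply(names(sim$truth$programs), function(p)
        GeneSet(p, sim$truth$programs[[p]], "planted program")),
        file.path(dir, "sets.gmt"))
    writeGmt(list(GeneSet("S", sim$truth$s_genes, "S phase markers")),
             file.path(dir, "s_genes.gmt"))
    writeGmt(list(GeneSet("G2M", sim$truth$g2m_genes, "G2M phase markers")),
             file.path(dir, "g2m_genes.gmt"))
    writeTransitionGraph(sim$graph, file.path(dir, "graph.tsv"))
    writeLines(sim$truth$tf_ids, file.path(dir, "tfs.txt"))
    truth <- sim$truth
    truth$cluster_means <- NULL    # large matrix; regenerate via simulateMsc
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
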