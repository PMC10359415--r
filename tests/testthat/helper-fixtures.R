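## Shared fixtures. The default simulation and its full analysis are
## expensive (~25 s together), so they are computed once per test run and
## memoized here.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulateMsc(simConfig(seed = 1))
  .fixture_env$sim
}

default_analysis <- function() {
  if (is.null(.fixture_env$ana))
    .fixture_env$ana <- analyzeSimulation(default_sim(), seed = 1)
  .fixture_env$ana
}

## one-sample, one-batch cell metadata for a set of cell ids
meta_df <- function(ids, sample = "s", batch = "b") {
  data.frame(sample_id = rep(sample, length(ids)),
             batch = rep(batch, length(ids)), row.names = ids)
}

## small deterministic CellMatrix: 6 genes x 8 cells, 2 samples / 2 clusters
tiny_cell_matrix <- function() {
  set.seed(42)
  counts <- matrix(rpois(48, 3), 6, 8,
                   dimnames = list(paste0("g", 1:6), paste0("c", 1:8)))
  CellMatrix(counts,
             data.frame(sample_id = rep(c("s1", "s2"), each = 4),
                        tissue_group = rep(c("perinatal", "adult"), each = 4),
                        batch = "b1",
                        cluster = rep(c("A", "B"), 4),
                        row.names = colnames(counts)))
}

## --- CLI fixtures -----------------------------------------------------

## small simulation config written to YAML plus the side inputs the screen
## subcommand needs; memoized per test run
cli_fixture_dir <- function() {
  if (!is.null(.fixture_env$cli_dir)) return(.fixture_env$cli_dir)
  root <- file.path(tempdir(), "senescreen-cli")
  dir.create(root, showWarnings = FALSE)
  cfg <- list(n_genes = 300, n_tfs = 8, n_cells = 80, program_size = 25,
              n_de = 15, regulon_size = 10, proteome_coverage = 220,
              seed = 5)
  yaml::write_yaml(cfg, file.path(root, "sim.yaml"))
  sim <- simulateMsc(do.call(simConfig, cfg))
  pb <- computeSizeFactors(makePseudobulk(sim$cells, by = "sample",
                                          minCells = 0))
  utils::write.csv(as.data.frame(logCpm(pb)), file.path(root, "rna.csv"))
  prot <- log2(SummarizedExperiment::assay(sim$proteome, "intensity") + 1)
  rownames(prot) <- SummarizedExperiment::rowData(sim$proteome)$gene_id
  utils::write.csv(as.data.frame(prot), file.path(root, "protein.csv"))
  writeLines(sim$truth$tf_ids, file.path(root, "tfs.txt"))
  writeLines(utils::head(sim$truth$de_up_perinatal, 10),
             file.path(root, "up.txt"))
  writeLines("early_stages: [C123]", file.path(root, "screen.yaml"))
  .fixture_env$cli_dir <- root
  root
}

run_subcommand <- function(root, label, args_fn) {
  out <- file.path(root, label)
  dir.create(out, showWarnings = FALSE)
  suppressWarnings(suppressMessages(senescreenMain(args_fn(out))))
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  setNames(unname(tools::md5sum(files)), basename(files))
}

expect_rerun_identical <- function(root, name, args_fn) {
  h1 <- run_subcommand(root, paste0(name, "_run1"), args_fn)
  h2 <- run_subcommand(root, paste0(name, "_run2"), args_fn)
  expect_identical(h1, h2)
  invisible(h1)
}

## pseudobulk table straight from a count matrix
pb_from_counts <- function(counts, group, batch = NULL) {
  cd <- data.frame(sample_id = colnames(counts), group = group,
                   row.names = colnames(counts))
  if (!is.null(batch)) cd$batch <- batch
  methods::new("PseudobulkTable",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(counts = counts),
                 colData = S4Vectors::DataFrame(cd)))
}
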