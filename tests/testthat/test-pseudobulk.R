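test_that("pseudobulk sums are exact and conserve total UMI", {
  counts <- matrix(c(1L, 0L, 2L,
                     0L, 3L, 0L), 3, 2,
                   dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  cm <- CellMatrix(counts, meta_df(c("c1", "c2")))
  pb <- makePseudobulk(cm, by = "sample", minCells = 0)
  expect_equal(unname(SummarizedExperiment::assay(pb, "counts")[, 1]),
               c(1, 3, 2))

  cm2 <- tiny_cell_matrix()
  pb2 <- makePseudobulk(cm2, by = c("sample", "cluster"), minCells = 0)
  expect_equal(sum(SummarizedExperiment::assay(pb2, "counts")),
               sum(SummarizedExperiment::assay(cm2, "counts")))
  expect_equal(ncol(pb2), 4)    # 2 samples x 2 clusters

  pb3 <- makePseudobulk(cm2, by = "sample", minCells = 0)
  expect_equal(ncol(pb3),
               length(unique(SummarizedExperiment::colData(cm2)$sample_id)))

  ## units below the cell floor are dropped with a warning
  cts4 <- matrix(2L, 4, 10, dimnames = list(paste0("g", 1:4),
                                            paste0("c", 1:10)))
  cm4 <- CellMatrix(cts4, data.frame(
    sample_id = rep(c("big", "small"), c(8, 2)), batch = "b",
    row.names = colnames(cts4)))
  expect_warning(pb4 <- makePseudobulk(cm4, by = "sample", minCells = 5),
                 "dropped")
  expect_equal(colnames(pb4), "big")
  expect_error(makePseudobulk(cm2, by = character(0)), "empty grouping")
})

test_that("size factors are median-of-ratios with geometric mean one", {
  m <- matrix(c(4L, 10L, 6L, 4L, 10L, 6L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("u1", "u2")))
  pb <- computeSizeFactors(pb_from_counts(m, c("a", "b")))
  expect_equal(unname(sizeFactors(pb)), c(1, 1))

  m2 <- m; m2[, 2] <- m[, 1] * 3L
  pb2 <- computeSizeFactors(pb_from_counts(m2, c("a", "b")))
  expect_equal(unname(sizeFactors(pb2)), c(1 / sqrt(3), sqrt(3)))

  ## random fixture vs a brute-force median-of-ratios oracle
  set.seed(12)
  m3 <- matrix(rpois(50 * 4, 60) + 1L, 50, 4,
               dimnames = list(paste0("g", 1:50), paste0("u", 1:4)))
  pb3 <- computeSizeFactors(pb_from_counts(m3, c("a", "a", "b", "b")))
  geo <- exp(rowMeans(log(m3)))
  sf_oracle <- apply(m3 / geo, 2, median)
  sf_oracle <- sf_oracle / exp(mean(log(sf_oracle)))
  expect_equal(unname(sizeFactors(pb3)), unname(sf_oracle))

  ## DESeq2 cross-check (it takes the median on the log-ratio scale, which
  ## differs only in how an even number of genes is interpolated)
  sf_deseq <- DESeq2::estimateSizeFactorsForMatrix(m3)
  expect_equal(unname(sizeFactors(pb3)),
               unname(sf_deseq / exp(mean(log(sf_deseq)))),
               tolerance = 1e-3)

  expect_error(computeSizeFactors(pb_from_counts(m[, 1, drop = FALSE], "a")),
               "two units")
})

test_that("NB Wald matches the Poisson GLM oracle as dispersion vanishes", {
  set.seed(2)
  ng <- 20
  mu <- exp(rnorm(ng, log(500), 0.5))
  cts <- sapply(1:8, function(j) rpois(ng, mu * if (j > 4) 1.5 else 1))
  dimnames(cts) <- list(paste0("g", 1:ng), paste0("u", 1:8))
  pb <- computeSizeFactors(pb_from_counts(cts, rep(c("a", "b"), each = 4)))
  de <- nbWaldDE(pb, group = "group", dispersion = 1e-8)
  sf <- sizeFactors(pb)
  g01 <- rep(c(0, 1), each = 4)
  oracle <- sapply(1:ng, function(i) {
    fit <- stats::glm(cts[i, ] ~ g01, family = poisson, offset = log(sf))
    summary(fit)$coefficients["g01", "z value"]
  })
  expect_lt(max(abs(de$stat - oracle) / abs(oracle)), 0.02)
})

test_that("swapping group labels negates every log2 fold change", {
  set.seed(3)
  cts <- matrix(rnbinom(100 * 8, mu = 80, size = 3), 100, 8,
                dimnames = list(paste0("g", 1:100), paste0("u", 1:8)))
  pb <- computeSizeFactors(pb_from_counts(cts, rep(c("a", "b"), each = 4)))
  de_ab <- nbWaldDE(pb, group = "group", ref = "a")
  de_ba <- nbWaldDE(pb, group = "group", ref = "b")
  expect_equal(de_ab$log2_fc, -de_ba$log2_fc, tolerance = 1e-8)
  expect_equal(de_ab$pvalue, de_ba$pvalue, tolerance = 1e-8)
})

test_that("BH adjustment is monotone in the p-ranking and bounded by 1", {
  set.seed(4)
  cts <- matrix(rnbinom(300 * 6, mu = 50, size = 3), 300, 6,
                dimnames = list(paste0("g", 1:300), paste0("u", 1:6)))
  pb <- computeSizeFactors(pb_from_counts(cts, rep(c("a", "b"), each = 3)))
  de <- nbWaldDE(pb, group = "group")
  ok <- !is.na(de$pvalue)
  expect_true(all(de$padj[ok] >= de$pvalue[ok]))
  expect_true(all(de$padj[ok] <= 1))
  o <- order(de$pvalue[ok])
  expect_true(all(diff(de$padj[ok][o]) >= -1e-12))
})

test_that("all-zero genes are excluded and reported", {
  cts <- matrix(5L, 10, 4, dimnames = list(paste0("g", 1:10),
                                           paste0("u", 1:4)))
  cts[3, ] <- 0L
  pb <- computeSizeFactors(pb_from_counts(cts, c("a", "a", "b", "b")))
  de <- nbWaldDE(pb, group = "group")
  expect_false("g3" %in% de$gene)
  expect_identical(attr(de, "excluded"), "g3")
})

test_that("planted tissue-group effects are recovered with the right sign", {
  sim <- default_sim()
  ana <- default_analysis()
  de <- ana$de_rna      # contrast: perinatal vs adult
  up_p <- de$log2_fc[match(sim$truth$de_up_perinatal, de$gene)]
  up_a <- de$log2_fc[match(sim$truth$de_up_adult, de$gene)]
  expect_gte(mean(up_p > 0, na.rm = TRUE), 0.95)
  expect_gte(mean(up_a < 0, na.rm = TRUE), 0.95)

  ## DESeq2 as an independent oracle on the same pseudobulk table
  cts <- SummarizedExperiment::assay(ana$pseudobulk, "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(ana$pseudobulk))
  cd$group <- relevel(factor(cd$group), "adult")
  cd$batch <- factor(cd$batch)
  dds <- DESeq2::DESeqDataSetFromMatrix(cts, cd, ~ batch + group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  shared <- intersect(de$gene, rownames(res))
  lfc_ours <- de$log2_fc[match(shared, de$gene)]
  lfc_deseq <- res$log2FoldChange[match(shared, rownames(res))]
  expect_gt(cor(lfc_ours, lfc_deseq, use = "complete.obs"), 0.95)
})
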