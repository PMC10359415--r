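test_that("log-CPM transform follows its formula", {
  cts <- matrix(c(0L, 999999L, 500L, 1000L), 2, 2,
                dimnames = list(c("g1", "g2"), c("u1", "u2")))
  v <- logCpm(cts)
  expect_equal(v["g1", "u1"], log2(0.5 / 1e6 * 1e6))   # exactly -1
  ## independent recomputation on a random fixture
  set.seed(31)
  m <- matrix(rpois(60, 40), 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("u", 1:6)))
  expect_equal(logCpm(m),
               log2(sweep(m + 0.5, 2, colSums(m) + 1, "/") * 1e6))
  expect_error(logCpm(cbind(m, u7 = 0L)), "zero-library")
})

test_that("quantile normalization has its defining properties", {
  ## identical columns are a fixed point
  m <- matrix(c(1, 5, 2, 1, 5, 2), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(quantileNormalize(m), m)

  ## worked 2-column example: both columns become the rank means
  m2 <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(quantileNormalize(m2)),
               cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  ## any input: all columns share the same sorted values; idempotent
  set.seed(32)
  m3 <- matrix(rnorm(60), 12, 5)
  q <- quantileNormalize(m3)
  sorted <- apply(q, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], tolerance = 1e-12)
  expect_equal(quantileNormalize(q), q, tolerance = 1e-12)

  expect_error(quantileNormalize(matrix(c(1, NA), 1)), "missing")
})

test_that("merged PCA separates modality on PC1 and group on PC2", {
  sim <- default_sim()
  ana <- default_analysis()
  sc <- ana$pca$scores
  ## PC1: all rna on one side of zero, all protein on the other
  expect_true(max(sc$PC1[sc$modality == "protein"]) < 0 ||
              min(sc$PC1[sc$modality == "protein"]) > 0)
  expect_true(sign(mean(sc$PC1[sc$modality == "rna"])) !=
              sign(mean(sc$PC1[sc$modality == "protein"])))
  ## PC2: positive silhouette-like separation of groups within modality
  for (mod in c("rna", "protein")) {
    a <- sc$PC2[sc$modality == mod & sc$group == "perinatal"]
    b <- sc$PC2[sc$modality == mod & sc$group == "adult"]
    expect_true(min(a) > max(b) || min(b) > max(a))
  }
  ## variance fractions are non-increasing and sum to <= 1
  expect_true(all(diff(ana$pca$varFrac) <= 1e-12))
  expect_lte(sum(ana$pca$varFrac), 1 + 1e-8)
})

test_that("duplicated samples get identical PCA scores; signs are fixed", {
  set.seed(33)
  m <- matrix(rnorm(80, 8), 10, 8,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  m[, 5:8] <- m[, 1:4] + 3   # second modality = offset copy
  m[, 8] <- m[, 7]           # duplicated sample
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(merged = m),
    colData = S4Vectors::DataFrame(
      modality = rep(c("rna", "protein"), each = 4),
      group = rep(c("x", "x", "y", "y"), 2),
      source_sample = paste0("s", 1:8), row.names = colnames(m)))
  op <- methods::new("OmicsPair", se)
  pca <- mergedPca(op)
  expect_equal(unname(unlist(pca$scores[7, 1:2])),
               unname(unlist(pca$scores[8, 1:2])))
  ## sign convention: largest-magnitude loading positive on each PC
  for (j in 1:2) {
    l <- pca$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("2D enrichment scores obey the rank-statistic identities", {
  set.seed(34)
  n <- 200
  x <- setNames(rnorm(n), paste0("g", 1:n))
  y <- setNames(rnorm(n), paste0("g", 1:n))
  ## the all-genes category scores exactly 0 in both dimensions
  all_cat <- GeneSet("all", names(x))
  res <- enrichment2d(x, y, list(all_cat))
  expect_equal(res$table$s_x, 0)
  expect_equal(res$table$s_y, 0)

  ## the single top-ranked gene scores (n-1)/n when min size allows it
  top <- names(which.max(x))
  res1 <- enrichment2d(x, y, list(GeneSet("top", top)), minSize = 1)
  expect_equal(res1$table$s_x, (n - 1) / n)

  ## |s| <= (n-m)/n for every category; invariance to monotone transforms
  cats <- lapply(1:15, function(i)
    GeneSet(paste0("c", i), sample(names(x), sample(3:30, 1))))
  res2 <- enrichment2d(x, y, cats)
  expect_true(all(abs(res2$table$s_x) <= (n - res2$table$n) / n + 1e-12))
  res3 <- enrichment2d(exp(x), y^3 + y, cats)   # both strictly monotone
  expect_equal(res2$table$s_x, res3$table$s_x)
  expect_equal(res2$table$s_y, res3$table$s_y)

  expect_error(enrichment2d(x, y, list(GeneSet("none", "absent"))),
               "no category")
})

test_that("planted concordant categories give positive Spearman concordance", {
  sim <- default_sim()
  ana <- default_analysis()
  x <- setNames(ana$de_protein$log2_fc, ana$de_protein$gene)
  y <- setNames(ana$de_rna$log2_fc, ana$de_rna$gene)
  ## 30 categories with graded shared shifts: mixtures of the planted
  ## perinatal-up and adult-up pools
  cats <- senescreen:::.with_seed(35, lapply(1:30, function(i) {
    nup <- round(30 * (i - 1) / 29)
    GeneSet(sprintf("cat%02d", i),
            c(sample(sim$truth$de_up_perinatal, nup),
              sample(sim$truth$de_up_adult, 30 - nup)))
  }))
  enr <- enrichment2d(x, y, cats)
  expect_gt(enr$spearman_rho, 0)
  expect_lt(enr$spearman_p, 0.05)
  expect_gt(sum(enr$table$significant), 0)
})

test_that("correlation matrices match the covariance formula", {
  set.seed(36)
  a <- matrix(rnorm(300), 100, 3,
              dimnames = list(paste0("g", 1:100), paste0("p", 1:3)))
  expect_equal(diag(correlationMatrix(a)), setNames(rep(1, 3), colnames(a)))
  b <- cbind(q1 = -a[, 1])
  expect_equal(unname(correlationMatrix(a, b)[1, 1]), -1)
  ## brute force against the covariance formula
  oracle <- matrix(NA_real_, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    u <- a[, i] - mean(a[, i]); v <- a[, j] - mean(a[, j])
    oracle[i, j] <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  }
  expect_equal(unname(correlationMatrix(a)), oracle)
  expect_error(correlationMatrix(cbind(a, const = rep(1, 100))),
               "zero-variance")
})
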