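## brute-force recovery-curve oracle: rank genes by value (desc, tie-break
## by a supplied permutation), accumulate the recovery curve step by step
aucell_oracle <- function(values, members, x, perm) {
  n <- length(values)
  k <- ceiling(x * n)
  ord <- order(-values, perm)
  raw <- 0; hits <- 0; maxraw <- 0
  m <- sum(names(values)[ord] %in% members)
  for (i in seq_len(k)) {
    if (names(values)[ord][i] %in% members) hits <- hits + 1
    raw <- raw + hits
    maxraw <- maxraw + min(i, m)
  }
  raw / maxraw
}

## CellMatrix whose logcounts assay holds arbitrary (possibly non-integer)
## expression values; the counts assay is a zero placeholder
make_cm <- function(values_by_cell) {
  vals <- do.call(cbind, values_by_cell)
  dimnames(vals) <- list(names(values_by_cell[[1]]),
                         paste0("c", seq_along(values_by_cell)))
  counts <- matrix(0L, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  cm <- CellMatrix(counts, meta_df(colnames(vals)))
  SummarizedExperiment::assay(cm, "logcounts") <- vals
  cm
}

test_that("activity reproduces the worked recovery-curve example", {
  ## 10 genes; regulon genes at ranks 2 and 4; x = 0.5 so k = 5:
  ## c = (0,1,1,2,2), raw = 6, max = 1+2+2+2+2 = 9, activity = 2/3
  v <- setNames(c(10L, 9L, 8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L), paste0("g", 1:10))
  cm <- make_cm(list(v))
  reg <- list(Regulon("tf", c("g2", "g4")))
  act <- scoreRegulons(cm, reg, topFraction = 0.5, seed = 1)
  expect_equal(unname(act[1, 1]), 2 / 3)

  ## regulon occupying the top ranks attains 1; none in top k gives 0
  expect_equal(unname(scoreRegulons(cm, list(Regulon("a", c("g1", "g2"))),
                                    topFraction = 0.5, seed = 1)[1, 1]), 1)
  expect_equal(unname(scoreRegulons(cm, list(Regulon("z", c("g9", "g10"))),
                                    topFraction = 0.5, seed = 1)[1, 1]), 0)
  expect_error(scoreRegulons(cm, reg, topFraction = 0), "topFraction")
})

test_that("activity matches the brute-force oracle on random rankings", {
  set.seed(21)
  n <- 40
  for (rep in 1:20) {
    vals <- setNames(sample(c(rpois(n, 4), rep(0L, 0))), paste0("g", 1:n))
    cm <- make_cm(list(vals))
    members <- sample(names(vals), sample(2:8, 1))
    x <- runif(1, 0.1, 0.9)
    act <- scoreRegulons(cm, list(Regulon("tf", members)),
                         topFraction = x, seed = 7)
    perm <- senescreen:::.with_seed(7, sample.int(n))
    expect_equal(unname(act[1, 1]),
                 aucell_oracle(vals, members, x, perm))
  }
})

test_that("activity is invariant to monotone transforms of a cell", {
  set.seed(22)
  vals <- setNames(rpois(60, 3) + runif(60) / 10, paste0("g", 1:60))
  members <- sample(names(vals), 6)
  cm1 <- make_cm(list(vals))
  cm2 <- make_cm(list(exp(2 * vals) + 1))   # strictly increasing transform
  a1 <- scoreRegulons(cm1, list(Regulon("tf", members)), seed = 3)
  a2 <- scoreRegulons(cm2, list(Regulon("tf", members)), seed = 3)
  expect_equal(a1, a2)
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("transition t equals the classical pooled two-sample t exactly", {
  set.seed(23)
  graph <- TransitionGraph(data.frame(parent = c("ROOT", "p"),
                                      child = c("p", "s")))
  for (rep in 1:50) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    act <- matrix(rnorm(n1 + n2), ncol = 1,
                  dimnames = list(NULL, "r1"))
    labels <- rep(c("p", "s"), c(n1, n2))
    tt <- transitionGlm(act, labels, graph)
    oracle <- t.test(act[labels == "s", 1], act[labels == "p", 1],
                     var.equal = TRUE)
    expect_equal(unname(tValues(tt)["r1", "s"]),
                 unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(unname(pValues(tt)["r1", "s"]), oracle$p.value,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and scaled activities behave as documented", {
  graph <- TransitionGraph(data.frame(parent = c("ROOT", "p"),
                                      child = c("p", "s")))
  ## identical distributions in parent and child -> t = 0, p = 1
  v <- rnorm(10)
  act <- cbind(r1 = c(v, v))
  tt <- transitionGlm(act, rep(c("p", "s"), each = 10), graph)
  expect_equal(unname(tValues(tt)["r1", "s"]), 0)
  expect_equal(unname(pValues(tt)["r1", "s"]), 1)

  ## positive rescaling of a regulon leaves t unchanged
  set.seed(24)
  act2 <- cbind(r1 = rnorm(30), r2 = rnorm(30))
  labels <- rep(c("p", "s"), each = 15)
  t_base <- tValues(transitionGlm(act2, labels, graph))
  act2[, "r2"] <- act2[, "r2"] * 7.3
  t_scaled <- tValues(transitionGlm(act2, labels, graph))
  expect_equal(t_base, t_scaled)

  expect_error(transitionGlm(act2, rep("p", 30), graph), "missing")
})

test_that("pattern grouping recovers planted archetypes and is stable", {
  set.seed(25)
  arche1 <- rep(20, 6); arche2 <- -arche1
  tv <- rbind(matrix(rep(arche1, 8), 8, byrow = TRUE),
              matrix(rep(arche2, 8), 8, byrow = TRUE)) +
        matrix(rnorm(96), 16)
  dimnames(tv) <- list(paste0("r", 1:16), paste0("s", 1:6))
  graph <- TransitionGraph(data.frame(parent = "ROOT", child = "s1"))
  tt <- methods::new("TransitionTable", tValues = tv,
                     pValues = tv * 0, pAdjusted = tv * 0, graph = graph)
  g2 <- groupPatterns(tt, k = 2, tDisplay = 10)
  expect_length(unique(g2[1:8]), 1)
  expect_length(unique(g2[9:16]), 1)
  expect_false(g2[1] == g2[9])

  ## k = 1 puts every displayed regulon in one group
  expect_length(unique(groupPatterns(tt, k = 1, tDisplay = 10)), 1)

  ## permuting regulon order leaves memberships invariant up to labels
  perm <- sample(16)
  tt_p <- methods::new("TransitionTable", tValues = tv[perm, ],
                       pValues = tv * 0, pAdjusted = tv * 0, graph = graph)
  gp <- groupPatterns(tt_p, k = 2, tDisplay = 10)
  expect_true(all(tapply(gp[names(g2)], g2,
                         function(x) length(unique(x))) == 1))

  expect_error(groupPatterns(tt, k = 20, tDisplay = 10), "display filter")
})

test_that("the planted master regulon rises at the root and falls in leaves", {
  sim <- default_sim()
  ana <- default_analysis()
  tv <- tValues(ana$transitions)
  master <- sim$truth$master_tf
  expect_gt(tv[master, rootStages(sim$graph)], 0)
  leaves <- setdiff(stages(sim$graph),
                    c(rootStages(sim$graph), graphEdges(sim$graph)$parent))
  expect_true(all(tv[master, leaves] < 0))
  ## display filter keeps the master regulon
  expect_true(master %in% displayedRegulons(ana$transitions))
})
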