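---
title: "Methods: senescence scoring, regulon dynamics and dual-omics TF screening"
author: "senescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: senescence scoring, regulon dynamics and dual-omics TF screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Cultured mesenchymal stromal cell (MSC) products are heterogeneous: during
in-vitro expansion a fraction of the cells drifts into cellular senescence,
losing proliferative capacity and immunosuppressive potency. `senescreen`
implements a pipeline for quantifying that drift from single-cell UMI
counts and for nominating candidate regulator transcription factors (TFs)
by integrating the single-cell transcriptome with a bulk proteome:

1. per-cell functional scores for gene programs (senescence, proliferation,
   DNA repair, immunosuppression, ...) and cell-cycle phase calls;
2. pseudobulk negative-binomial differential expression with a batch
   covariate;
3. rank-based regulon activity per cell and a per-stage transition model
   over a branching cluster trajectory;
4. an in-silico-bulk/proteome merge with quantile normalization, PCA and
   two-dimensional annotation enrichment;
5. a two-arm TF candidate screen and module extraction around a candidate.

A synthetic-data generator with planted ground truth makes all of this
testable end to end without external data; the package's tests and the
`scripts/acceptance.R` report are built entirely on it.

# Models and procedures

## Normalization and gene-set scores

Counts are depth-normalized to 10,000 molecules per cell and
log-transformed: `value[g,c] = log1p(count[g,c]/L_c * 1e4)` with `L_c` the
cell's total UMI count. A gene set's score for a cell is the plain average
of these normalized values over the set's genes. No control-gene
subtraction is applied to functional scores: the average-expression
definition keeps scores on the expression scale and comparable across
sets. Set genes absent from the matrix are dropped rather than
zero-filled, because zero-filling would penalize panels measured against a
different gene universe; the number of dropped genes is logged.

## Cell-cycle phase

Phase scoring is the one place where a signed score is needed (a cell is
"not cycling" when its S and G2M scores are both non-positive), so here
the score is the set average minus the average of expression-matched
control genes. Controls are drawn per marker gene, without replacement and
under a fixed seed, from bins of genes with similar across-cell mean
expression (genes ranked by mean, cut into `nBins = 24` equal-size bins;
`nCtrl = 100` draws per marker). A cell is called S or G2M by the larger
positive score, ties broken toward S (documented, arbitrary), and G1
otherwise.

## Pseudobulk differential expression

Cells are summed into pseudobulk units -- by sample ("in-silico bulk") or
by sample and cluster -- so the differential test models biological rather
than cell-level replication. Units with fewer than `minCells = 10` cells
are dropped by default (configurable; the sums are otherwise exact and
conserve total UMI). Size factors are median-of-ratios (the per-unit
median of count/geometric-mean over genes positive in every unit),
rescaled to geometric mean one, with a library-size fallback when no gene
is all-positive.

Per gene we fit a negative-binomial GLM with log link, variance
`mu + phi * mu^2`, offsets `log(size factor)` and design
`~ batch + group`. The dispersion `phi` is a per-gene method-of-moments
estimate on size-factor-normalized counts with a floor of `1e-8`. Two
numerical choices deserve emphasis:

* **Moments are pooled within design cells.** `phi` is estimated from the
  within-(group x batch) means and variances, pooled with `n_j - 1`
  weights. Estimating it from the marginal moments instead would absorb
  any true group effect into the dispersion, which algebraically caps the
  Wald statistic near `sqrt(n_units)` for strongly regulated genes and
  destroys power on small panels; the within-cell estimator is identical
  under the null and unbiased under alternatives.
* **The Wald p-value uses a t reference.** With ~12 units the plug-in
  dispersion is itself noisy; normal asymptotics are anticonservative
  (empirical type-I error ~0.09 at nominal 0.05 in our null simulations).
  Referring `beta/SE` to a t distribution on the residual degrees of
  freedom restores calibration (~0.06) without changing the statistic.

There is no dispersion shrinkage across genes, no independent filtering
and no outlier handling: the pipeline's claims are sign- and
proportion-level, and those refinements belong to dedicated DE packages.
Genes with all-zero counts are excluded and reported; non-converged IRLS
fits (cap 100 iterations) are flagged with `p = NA`. BH correction is
applied across tested genes.

## Regulon activity and the transition model

A regulon is a TF plus its target list (supplied externally, e.g. from a
network-inference step; this package does not infer regulons). Activity is
the area under the recovery curve of the regulon's genes within the
top-ranked fraction `x = 0.05` of a cell's genes, divided by its maximum
`sum(min(i, m))`, so it lies in `[0, 1]` and depends only on within-cell
ranks -- any strictly increasing transform of a cell's expression leaves
it unchanged. Ties (notably the zero block of a UMI profile) are broken by
one seeded permutation of gene indices shared across all cells, which
keeps the score deterministic and unbiased.

Stage-wise regulon dynamics are modeled on a branching cluster graph
(every non-root stage has exactly one parent). For a stage `s` with parent
`p`, the model is an ordinary linear regression of activity on the stage
indicator over the cells of `p` and `s`; the reported t-value is the
indicator coefficient over its standard error, which equals the classical
pooled two-sample t-statistic exactly, with `n_p + n_s - 2` degrees of
freedom. A Gaussian identity model is used deliberately: activities are
bounded but sit well inside (0, 1) in practice, and the t-value scale is
what the display filter and screen thresholds are defined on. Each root
stage is contrasted against all other cells, so early-activated regulons
acquire positive root t-values -- this is our reading of how "activated in
the early clusters" acquires a sign. P-values are BH-adjusted within each
stage column. For display and downstream grouping, only regulons with at
least one `|t| > 20` are kept (configurable); the retained t-value rows
are clustered with Ward linkage on Euclidean distances and cut into
`k = 5` activation-pattern groups.

## Dual-omics integration

In-silico bulk counts are transformed to moderated log2 CPM,
`log2((count + 0.5)/(libsize + 1) * 1e6)`; proteome peak areas enter as
per-sample median-centered log2 intensities. Precision weights are
deliberately omitted -- the merged matrix feeds a PCA, not a weighted
regression. Both modalities are restricted to their shared gene set
(matching is by exact gene-symbol string; protein groups mapping to
several symbols must be resolved upstream) and quantile normalized
together, giving every column the same value distribution (ties within a
column receive the mean of their ranks' reference values; the operation is
idempotent). PCA is a gene-centered SVD with samples as observations; each
component's sign is fixed so its largest-magnitude loading is positive,
making score plots reproducible bit for bit.

Two-dimensional annotation enrichment scores each gene category on two
per-gene statistics (protein and transcript fold changes) as
`s = (2/n) * (mean member rank - (n+1)/2)` per dimension, a rank statistic
in (-1, 1) that is zero for the all-genes category and bounded by
`(n-m)/n`. Because the exact two-dimensional test variant used by the
original desktop software is unspecified, significance is a documented
composite: a two-sided Mann-Whitney test per dimension, a factor-2
Bonferroni within the category, and BH across categories; the s-scores
themselves are unaffected by this choice. Concordance between modalities
is summarized as Spearman's correlation between `s_protein` and `s_rna`
across tested categories.

## TF candidate screen and module extraction

The screen intersects two arms:

* **Correlation arm.** For each TF in the supplied universe, Pearson
  correlation between its expression vector and the mean profile of the
  dual-omics upregulated non-TF genes across samples, separately per
  modality (the protein side uses the TF's protein row when quantified;
  otherwise the TF is evaluated on RNA alone and flagged). A TF passes at
  `r > 0.9` with one-sided `p < 0.05` (t distribution, `n - 2` df;
  one-sided because the hypothesis is positive association) in every
  evaluated modality. The aggregate-profile correlation is the default
  because the screen reports a single correlation per TF; a per-gene
  variant with a qualifying fraction is available behind a config switch.
* **Regulon arm.** TFs whose regulon has transition `t > 30` with
  `p < 0.05` in at least one early (non-senescent) stage.

Module extraction around a candidate keeps non-TF genes whose transcript
profile correlates with the TF at `r > 0.8` (BH-adjusted one-sided
`p < 0.05` over all tested non-TF genes) and that are upregulated toward
the target group in both omics (`padj < 0.05`, positive fold change). The
correlation is computed on the transcript matrix; the dual-omics
requirement enters through the DE filter, which is how "supported by both
omics" is operationalized here.

# The synthetic-data generator

`simConfig()`/`simulateMsc()` generate a dataset whose planted structure
exercises every stage of the pipeline:

* **Design.** Seven clusters `C1..C7` on the branching trajectory
  `C123 -> C4 -> {C5, C6, C7}` (the three proliferative clusters are
  pooled into one root stage for transition analysis, as the cluster graph
  treats them as a single pre-transition population); six perinatal and
  six adult samples in three batches of four, 500 cells per sample. The
  tissue groups differ in cluster composition (perinatal ~70% early
  clusters, adult ~15%) and in 80 planted DE genes per direction at
  log2FC 1 -- composition plus planted effects, nothing hard-coded beyond
  that.
* **Counts.** For each cell, gene rates are a softmax over baseline
  log-rates (N(0,1) per gene) plus cluster program effects, tissue-group
  effects, per-batch gene offsets (sd 0.1) and per-cell latent regulon
  activities; counts are NB with `variance = mu + phi*mu^2`, `phi = 0.3`,
  library sizes log-normal(log 5000, 0.3). Program effects act on
  log-rates before the softmax, so library size and composition stay
  decoupled.
* **Programs.** Four disjoint 100-gene programs (proliferation,
  senescence, UPR, immunosuppression) with cluster weights that make
  senescence rise monotonically from root to leaves, the UPR specific to
  `C5`, and proliferation/immunosuppression highest in the early clusters.
  The first 60 proliferation genes double as the S/G2M marker lists.
* **Regulons.** Forty TFs with 30-gene regulons. The master TF's regulon
  is activated (log-effect 1.0 per unit activation) in the early clusters,
  half-activated in `C4` and off in the leaves; four decoy regulons are
  specific to each of `C4`, `C5`, `C6` and `C7` (together with the master
  these realize five distinct activation-pattern archetypes); the
  remaining regulons carry per-cell co-expression noise (sd 0.3) but no
  stage dynamics. The master TF gene itself is additionally upregulated in
  the perinatal group (log2FC 1.5), reflecting that a master regulator of
  the non-senescent state is itself group-differential -- without this the
  proteome measurement noise alone would bound its protein-side
  correlation below any stringent threshold.
* **Proteome.** For each sample, `log2(in-silico-bulk CPM + 1)` plus a
  per-gene modality offset (sd 2.0, shared across samples -- this is what
  makes PCA separate modalities on PC1) plus N(0, 0.4) measurement noise,
  exponentiated back to peak-area-like intensities; 1400 of the 2000 genes
  are "detected", drawn once per seed.

What the generator deliberately does **not** emulate: ambient RNA,
doublets, batch-specific dropout curves, protein groups with ambiguous
gene mapping, cell-cycle structure beyond the planted marker programs, and
any form of trajectory noise (cluster labels are exact). Passing tests on
this generator therefore demonstrate that the statistical machinery
recovers planted structure under idealized labeling, not that the pipeline
is robust to clustering errors or library artifacts in real data.

# Problem sizes and runtime choices

The default study (12 samples x 500 cells x 2000 genes) runs end to end in
roughly ten seconds per seed on one CPU; the packaged acceptance report
re-runs the full pipeline on ten seeds, a 2500-gene null calibration and
the oracle checks in under five minutes. Unit tests use smaller
configurations (40-800 cells, 150-300 genes) chosen so each planted effect
is still unambiguous at test tolerances.

# Known limitations

* Dispersion is per-gene method-of-moments with a floor -- no
  empirical-Bayes shrinkage -- so per-gene power at very small unit counts
  is below what shrinkage-based DE tools achieve; conclusions should stay
  at the sign/proportion level.
* The transition model is Gaussian on bounded activities; if activities
  concentrate near 0 or 1 a quasi-binomial variant would be more
  appropriate (not implemented).
* Gene identifiers are opaque case-sensitive strings; no symbol/accession
  mapping is attempted. Multi-omics users must pre-map protein groups.
* The 2D enrichment significance composite is a stand-in for an
  unspecified desktop implementation; only the s-scores should be compared
  across tools.
* The cluster labels and the transition graph are inputs. Clustering,
  pseudotime and regulon inference are out of scope.
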