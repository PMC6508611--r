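---
title: "Scoring drug efficacy from dual-baseline transcriptomes"
author: "TxProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug efficacy from dual-baseline transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TxProfiler)
```

## The problem

When several drugs are profiled against the same disease, a single-control
differential-expression analysis answers only "which genes does each
treatment change?". With *two* controls — healthy animals and untreated
diseased animals — far more can be asked: does a treatment return diseased
expression to healthy levels, does it leave disease-associated genes
deregulated, and does it perturb genes that the disease never touched?
TxProfiler implements this dual-baseline framework for designs such as
anti-TNF biologics tested in a TNF-transgenic polyarthritis model: one
healthy-control arm, one disease-control arm, and several treatment arms
(therapeutic or prophylactic timing).

All inputs are log2-scale expression values summarised to gene level
(e.g. RMA-normalised microarray intensities), genes in rows, samples in
columns. Probe-level preprocessing is out of scope; genes must be measured
in all samples (rows with missing values are dropped at load).

## Differential expression: one-way ANOVA with Dunnett contrasts

For every gene a pooled-variance one-way layout is fitted across *all*
conditions. Each non-baseline condition is compared against the baseline
(healthy or diseased control), giving a log2 fold-change (difference of
group means — the data are already log2) and a t statistic on the pooled
residual variance. Because each gene carries a *family* of many-to-one
comparisons, the adjusted p-value is Dunnett's two-sided family-wise
correction: `P(max_j |T_j| >= t)` under the multivariate t null with the
correlation structure implied by the group sizes. A gene is flagged DE
when `|log2FC| >= 1` and adjusted `p <= 0.05` — thresholds chosen, as is
standard, to select roughly the 2-sigma tail of the fold-change
distribution; both are configurable (`frameworkConfig()`).

Numerical choices:

* The multivariate-t tail is evaluated with `mvtnorm::pmvt`
  (quasi-Monte-Carlo, absolute tolerance 1e-5) on a grid of |t| values
  (step 0.05, capped at 12) and interpolated; the grid is forced monotone
  and cached per design, so a 20 000-gene study costs a few seconds. With
  a single comparison the adjusted p short-circuits to the exact two-sided
  t distribution.
* Genes with zero total variance are defined non-significant (log2FC 0,
  p = 1) rather than undefined.
* The Dunnett correction operates *within* a gene. An additional
  Benjamini–Hochberg correction *across* genes is available
  (`geneFDR = TRUE`) but off by default, matching the classical
  ANOVA+Dunnett reading of "adjusted p-value".

`dualBaseline()` runs the contrast twice — against the healthy and against
the disease control — on the same gene universe.

## DE gene sets and the trichotomy

Three nested sets summarise a study (`buildDESets()`): the
disease-associated profile (DE in disease vs healthy), its extension by
genes DE vs healthy under at least one treatment, and the full union
adding genes DE vs the disease control under at least one treatment.

Per treatment, the disease profile partitions into **restored** (no
longer DE vs healthy under treatment) and **not restored** (still DE);
genes DE under treatment but absent from the disease profile are
**altered** — secondary, off-target effects (`trichotomize()`). "Altered"
is defined against the healthy baseline by default; an optional inclusive
mode also counts genes DE only against the disease control, since the
full-union set mixes both baselines. Exclusive (UpSet-style) intersection
counts across treatments come from `exclusiveIntersections()`, with plain
total overlaps from `setOverlaps()` because both flavours are commonly
quoted.

## Distances, efficiency scores and 2D coordinates

The distance between two treatment profiles over N genes is the mean
absolute difference of their per-gene log2 fold-changes; against the
all-zero profile it is the *distance from the healthy state*, the
package's one-number proxy for efficiency (`distanceFromWT()`).

For a functional category f and treatment P, the efficiency score is

    E(P, f) = log10( agg|log2FC vs disease| / agg|log2FC vs healthy| )

over the category's DE genes: positive scores mean the treatment moved
the category far from the diseased state while staying close to healthy.
The aggregation `agg` has two defensible readings and both are
implemented: `mean_of_abs` (mean of absolute values; the default) and
`abs_of_mean` (absolute value of the mean, where opposite-sign changes
cancel — which makes expression *reversals* score very differently). The
denominator is guarded by `epsilon = 1e-8` and scores are capped at ±12
for reporting. `category2DCoordinates()` also returns the per-category
mean log2FC vs healthy (x) and vs disease (y), the coordinates used for
2D treatment-profile representations; categories with fewer than
`minCategorySize = 3` DE genes are skipped rather than scored on noise.

## Clustering

DE genes are clustered on their cross-condition log2FC-vs-healthy
profiles (disease plus each treatment arm as columns) with Ward's
minimum-variance criterion on Euclidean distances (`hclust` method
`ward.D2`, the variance-correct form). The cluster number is chosen by
maximising the mean silhouette width over k = 2..15, ties broken toward
the smaller k (parsimony); all-identical profiles yield k = 1 with a
warning. Column order is irrelevant to the labels.

## Random-forest classification

`rfSelect()` trains many forests (default 1000 models of 500 trees,
`mtry = 10`) on fresh stratified 70/30 splits and keeps the model with
the lowest out-of-bag error (ties to the lowest index). OOB error is
computed on each model's 70% training portion — standard bagging OOB —
because the 30% is reserved as a test set; both the test and the OOB
confusion matrices are reported, along with mean-decrease-in-Gini
importances (ties in the ranking break alphabetically). Features are
either genes (expression rows over a DE set) or functional categories
(mean expression over the category's DE genes, `categoryFeatures()`) —
the pathway-aggregated representation that tends to classify noisy
block-structured signal at least as well as individual genes. Two sample
modes mirror typical use: all samples including the controls, or
treatments only. `pcaEmbed()` projects samples onto the first two
principal components of the top-ranked features.

## Enrichment

`hypergeomEnrich()` is a plain upper-tail hypergeometric
over-representation test with Benjamini–Hochberg correction across the
tested categories, with the *measured* genes (not the genome) as the
default universe. Web-service correction algorithms used in interactive
tools are deliberately not reproduced, so term lists should be read as
qualitative.

## The synthetic generator

`generateStudy()` simulates the full design with planted ground truth so
every downstream stage is testable without external data.
`antiTNFStudyTruth()` encodes the emulated study conditions: 10 healthy and
13 diseased controls, four 10-replicate therapeutic arms and one
3-replicate prophylactic arm; 404 over- and 463 under-expressed disease
genes; per-arm restoration fractions chosen so the expected non-restored
counts are 3 / 25 / 92 / 106 / 175; arm-specific altered blocks of sizes
170 / 0 / 30 / 217 / 175; the prophylactic arm carries the only non-zero
reversal fraction and its altered block is displaced opposite to the
nominal direction (early-intervention over-compensation).

Generative model: gene baselines are drawn Uniform(4, 12) on the log2
scale (a realistic microarray intensity range), residual noise is
independent Gaussian with sd 0.25, and the planted effect size is 2.5 —
chosen so detection of planted effects is near-saturated, matching a
strongly separated healthy/diseased design, while |log2FC| of null genes
stays an order of magnitude below the threshold. The annotation contains
one category per planted block plus 50 decoy categories of 10–200 random
genes, so enrichment specificity is testable.

What the generator does **not** emulate: mean–variance trends, probe-level
artifacts, batch effects, correlated co-expression within blocks, and
cluster-structured treatment responses — each gene's restored/reversed
fate is drawn independently. Two consequences are worth knowing. First,
passing tests demonstrate correct recovery of planted structure, not
robustness to the correlation structure of real arrays. Second, because
per-gene fates are independent, the disease profiles of an emulated-design
simulation have combinatorial rather than block-like response patterns,
so the silhouette-selected cluster number reflects that granularity
instead of a planted k; the dedicated cluster-number recovery checks
therefore plant explicit well-separated blocks.

```{r quick-tour, eval = FALSE}
sim <- generateStudy(antiTNFStudyTruth(), nGenes = 6000, seed = 1)
de  <- dualBaseline(sim$study)
sets <- buildDESets(de$vsHealthy, de$vsDisease)
tri  <- trichotomizeAll(sim$study, de$vsHealthy)
sapply(tri, function(x) lengths(x))
```

## Problem sizes and reproducibility

The test suite and the acceptance script run the whole pipeline at sizes
a laptop handles in minutes: simulations of 1 600–6 000 genes (the
planted structure occupies 1 459), 100-model random-forest loops (the
1000-model default is retained for full reproduction runs), 20 null
studies of 2 000 genes for the Dunnett calibration check, and a
1 000 000-draw brute-force check of the Dunnett tail at a small design.
All randomness flows from explicit integer seeds; identical seeds give
byte-identical simulated studies and identical forest selections. The
quasi-Monte-Carlo integration inside the Dunnett tail runs under a fixed
internal RNG state and restores the caller's stream.

## Known limitations

* Exact p-value reproduction against any specific commercial ANOVA
  implementation is not promised; DE calls are validated through
  calibration and oracle checks instead.
* The efficiency score is descriptive — no significance test accompanies
  it, and categories below the minimum size are skipped, not scored.
* A 3-replicate arm leaves two training samples per forest split; its
  single held-out sample can be misassigned to the healthy class when the
  arm restores nearly all disease genes. That is a property of the design
  being emulated, not of the classifier implementation.
* Enrichment results are qualitative (hypergeometric + BH, measured-gene
  universe); GO-graph propagation and curated TF-target repositories are
  user-supplied via GMT.
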