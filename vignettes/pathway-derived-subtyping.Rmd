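---
title: "Pathway-derived subtyping: models, choices, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-derived subtyping: models, choices, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdskit)
```

## The problem

Transcriptional subtyping of colorectal tumors is usually driven by
gene-level clustering. `pdskit` implements the alternative route of
classifying tumors by *pathway-level* activity: every sample is scored
against a catalogue of curated gene sets with a single-sample enrichment
statistic, subtypes are discovered by clustering samples in that pathway
space, and a probability-calibrated classifier then assigns new samples to
one of three pathway-derived subtypes (PDS1, PDS2, PDS3) or to a "mixed"
category when no class reaches the probability threshold. On top of the
classifier the package provides derived transcriptomic indices: a stem
maturation index (SMI) built from MYC-target and polycomb (PRC)-target
modules, a PCNA-tradition proliferative index, a replication-stress score,
and LGR5+ crypt-base-columnar (CBC) / ANXA1+ regenerative (RSC)
stem-signature scores, all applicable to bulk cohorts and per-cell to
single-cell matrices.

## Enrichment statistics

**ssGSEA.** Expression enters only through within-sample ranks
(1..N, N = highest; average ties). For a set S, genes are walked in order
of decreasing rank (ties broken by gene index for determinism); the in-set
running fraction accumulates `rank^tau` mass normalized by the set total,
the out-of-set fraction steps `1/(N - |S|)`, and the enrichment score is
the **sum** of (in − out) over all N positions — the integrated statistic,
not the maximum deviation. `tau` defaults to 0.25, the de facto default of
the single-sample method this statistic follows; it is exposed because the
upstream literature does not pin it. Rank dependence makes the score
invariant to any strictly monotone per-sample transform, which is why the
loader never normalizes expression: platform normalization is a
cohort-level concern upstream of this package.

With `normalize = TRUE` the whole score matrix is divided by its global
`max − min` and the two extremes are stored. Storing them is load-bearing:
new cohorts are scored **on the training scale** via
`score_with_stored_range()`, not on their own range, so prediction-time
scores are comparable with the training scores.

**GSVA variant.** The replication-stress score uses the kernel-CDF
variant: per gene, a Gaussian-kernel cumulative density across samples
(bandwidth = per-gene SD / 4, floored at 1e-8 so zero-variance genes are
defined rather than fatal), then per-sample ranking, symmetrization about
the middle rank, and a weighted Kolmogorov–Smirnov walk whose score is the
maximum positive plus maximum negative deviation (`gsva_max_diff = TRUE`).
At least 4 samples are required for the kernel estimate to be meaningful.

Both engines are vectorized; the test suite checks them against
independent position-by-position loop oracles (1e-12 for ssGSEA, 1e-9 for
GSVA) on randomized toys.

## Class discovery

The score matrix is embedded in two dimensions with t-SNE (perplexity 30
clipped to the admissible `(n − 1)/3` bound, 1000 iterations, mandatory
seed recorded in the result) and each dimension is standardized before
k-means (25 restarts, best within-cluster sum of squares, labels
renumbered so cluster 1 is the largest). k is selected jointly by mean
silhouette width, the within-cluster-SS elbow curve, and cluster-wise
bootstrap Jaccard stability (100 resamples; a cluster solution is "stable"
at the conventional 0.75 floor): the chosen k maximizes silhouette among
stable k, falling back to the overall silhouette argmax with a warning
flag when nothing is stable. Clustering operates on the 2-D embedding by
default (matching the discovery procedure this package follows);
`cluster_on_scores = TRUE` clusters the full score matrix for sensitivity
analysis.

A caveat found while testing: on a *null* isotropic Gaussian the k = 2
bootstrap Jaccard is ~0.78 — a 2-split along a fixed sample's elongation
axis is genuinely reproducible under resampling — so the stability floor
alone does not certify structure at k = 2; k ≥ 3 splits of null data do
fall below the floor. The joint use of silhouette and stability is what
carries the decision.

## Feature selection

"Subtype-specific" is operationalized as: a set is assigned to subtype g
iff its mean score in g is strictly the maximum across subtypes **and**
above the grand mean; this is the most literal reading that yields a
partition. Redundancy is then pruned greedily on the across-sample Pearson
correlation matrix: while any |r| exceeds the 0.9 cutoff, the member of
the most-correlated pair with the larger mean absolute correlation to the
remaining sets is removed (ties by set name), which makes the result
independent of input order; absolute correlation is used because the
upstream description names only the cutoff. Constant-score sets have
undefined correlation and are retained (treated as r = 0).

## Classifier

Training stores everything prediction needs in one JSON archive: the
selected sets with their gene memberships, the training min/max, the
reference-batch statistics, and the SVM with calibration. Prediction runs
ssGSEA on the model's sets, scales by the stored extremes, aligns the new
cohort to the training batch with reference-batch ComBat (parametric
empirical-Bayes location/scale; the reference defines the standardization
and is never altered; a single target sample falls back to location-only
adjustment), and applies a one-vs-one RBF-SVM.

The SVM dual is solved exactly with a QP solver (ridge 1e-8 for
definiteness). Hyperparameters are tuned by leave-one-out cross-validation
over cost {0.25, 0.5, 1, 2, 4, 8} and a kernel width grid of the median
heuristic ×{0.1, 1, 10}; ties prefer the smaller cost then the smaller
width. Per-pair probabilities are Platt sigmoids fitted on **5-fold
cross-validated** decision values (training-value fits are degenerate on
separable data), with prior-corrected targets; class probabilities come
from pairwise coupling (least-squares KKT system, clipped and
renormalized). A sample is labeled with the argmax class iff its maximum
probability reaches the threshold (default 0.6; 0.8 as the stringent
preset), otherwise "mixed" — so raising the threshold can only convert
class calls to mixed.

### Mixed-call calibration: a known limitation

In the synthetic world used for testing (below), training cohorts at
effect size 2 are linearly separable in score space. Platt sigmoids fitted
on separable data are steep, and a 50/50 blend of two subtype profiles
lands at a median maximum probability of ~0.62 — just above the 0.6
threshold — so only ~4–9% of a planted 15% blend fraction is called mixed
at 0.6 (at the stringent 0.8 threshold the planted fraction is recovered
within a point or two). This is not specific to this implementation:
libsvm (scikit-learn `SVC(probability=True)`) reproduces the same
shortfall (3–7%) on identical feature matrices. The corresponding
acceptance test is deliberately left failing as a faithful record. On real
tumor cohorts, which are not separable, the sigmoids are flatter and the
mixed category behaves as intended.

## Derived indices

* **SMI** = min–max rescale of (PRC-target score − MYC-target score) onto
  [−1, 1] **within the supplied cohort**; the rescale is cohort-relative,
  so SMI values are not comparable across independently scored cohorts. A
  degenerate cohort (all differences equal) maps to 0. High SMI =
  differentiated-like, low = stem-like.
* **Proliferative index** = per-sample median over a PCNA-associated
  signature (median follows the metagene tradition; the mean is available
  via a flag since the upstream aggregation is not restated).
* **Replication stress** = per-sample sum of GSVA scores over ~20
  cell-cycle/DNA-repair sets in bulk (left unscaled; only the single-cell
  variant is rescaled upstream); per-cell sum of ssGSEA scores rescaled to
  [−1, 1] in single-cell mode.
* **CBC/RSC** scores are plain unnormalized ssGSEA; **tertile labels**
  call a cell "A-high" iff score A is in the top tertile and B in the
  bottom one (mutually exclusive and exhaustive with "B-high"/"neither").

## The synthetic world

`simulate_cohort()` states the testing world: 150 samples × 1200 genes by
default, 30 disjoint gene sets of 30 genes (about the median size of
curated pathway sets after a min-size-10 filter), half of them informative
and assigned round-robin to k = 3 subtypes; informative member genes are
shifted by effect_size × noise_sd (default 2 × 1) in their subtype's
samples on a Gaussian log-like background; mixed samples take half-shifts
from two subtypes; optional per-batch location shifts. Set structure is a
deterministic function of the size parameters, so cohorts drawn with
different seeds share gene sets and serve as train/test pairs. The
generator emulates *ordering structure only*: no count noise,
overdispersion, dropout, or gene–gene correlation beyond set membership —
a green test establishes correctness of the pipeline's logic on planted
structure, not performance on real tumors.

`simulate_differentiation_axis()` plants a latent t ~ Uniform(0, 1) per
cell, scales MYC-target genes by (1 − t) and PRC-target genes by t
(amplitudes spread over [1.5, 2.5]) over a uniform fixed background, plus
noise. In the noiseless limit the PRC-minus-MYC difference is *strictly
monotone* in t, so Spearman correlation is exactly 1; Pearson cannot reach
exactly 1 because a rank-based score is a step function of a continuous
latent (it exceeds 0.999 in practice). The exactness clause of the SMI
acceptance test therefore asserts Spearman = 1 (±1e-6) plus Pearson ≥
0.99, and the noisy clause asserts Pearson ≥ 0.9 as specified.

## Numerical choices

* ssGSEA tie order within equal ranks: ascending gene index (determinism).
* Range normalization over the entire matrix, not per set — this is what
  makes the stored extremes reusable at prediction time.
* ComBat variance floor 1e-8; reference variance uses the /n convention of
  the standardization step, target batch scale the /(n−1) estimator.
* QP ridge 1e-8; support vectors at alpha > 1e-8 × cost; bias from free
  support vectors when any exist, else from all.
* Pairwise coupling solves the KKT linear system directly; negative
  components (rare, numerically induced) are clipped and renormalized.
* k-means restarts: 25 (10 inside the bootstrap loop, runtime only).
* Probe collapse keeps the probe with the highest across-sample mean;
  winners keep their original row order.

## Known limitations

* SMI and single-cell replication stress are cohort-relative rescales.
* The classifier is three-class by contract; it will not train on 2-class
  labelings.
* Mixed-call sensitivity at the default threshold degrades when training
  classes are perfectly separable (see above).
* The generator's Gaussian world has no library-size, dropout, or
  batch-by-class confounding structure; ComBat correctness is tested on
  location/scale shifts only.
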