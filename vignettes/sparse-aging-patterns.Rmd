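---
title: "Extracting covariance patterns of brain aging by sparse representation"
author: "sparsevbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting covariance patterns of brain aging by sparse representation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Gray-matter (GM) density declines with age, but not uniformly: some regions
shrink directly and strongly, while others change so subtly that no
single-voxel test detects them — yet their volume co-fluctuates with that of
strongly declining regions, so that *jointly* they carry discriminative
information about age. Classical voxel-based morphometry (VBM) ranks each
voxel by a univariate statistic (a two-sample t between young and old
cohorts) and therefore misses this second, covariance-borne component.

`sparsevbm` implements a multivariate pattern analysis (MVPA) pipeline that
recovers both components. Subjects' smoothed GM density maps are flattened
into a subject-by-voxel matrix \(A\) (rows standardized per voxel), the
cohort label vector \(y \in \{+1, -1\}^N\) (+1 young, −1 old) is treated as
the target of a sparse representation

\[
\min_w \|w\|_1 \quad \text{s.t.} \quad A w = y,
\]

and voxels are ordered by a recursive selection built on this program. The
pipeline then classifies with a linear max-margin classifier (SVM), reports
generalization rate / sensitivity / specificity (GR/SS/SC), builds a
cross-validated consensus pattern, and characterises it cluster by cluster.

## The linear program and its solver

With \(w = u - v\), \(u, v \ge 0\), the 1-norm objective becomes
\(\sum_j (u_j + v_j)\) subject to \([A, -A](u; v) = y\) — a non-negative
linear program. No LP solver is available as an R dependency in this stack,
so the package ships a two-phase revised simplex specialised to this basis
pursuit structure (`src/bp_simplex.cpp`):

* the \(\pm a_j\) column mirroring is exploited so pricing costs one
  \(m \times K\) product per window rather than \(m \times 2K\);
* partial (windowed) pricing keeps iterations cheap; optimality is declared
  only after a full pass over all windows finds no candidate, so the
  returned vertex is exact;
* the basis inverse is maintained explicitly (the row count is the number
  of training subjects, a few hundred at most) with product-form updates
  and periodic refactorisation; long degenerate runs switch to Bland's rule.

Because the solution is a simplex vertex, its support holds at most one
nonzero per constraint row, and `solve_min_l1()` verifies
\(\|Aw - y\|_\infty \le 10^{-7}\) (weights below \(10^{-8}\) count as
zero — double-precision LP defaults). Unsatisfiable systems return an
explicit `"infeasible"` status rather than an error, since the recursion
treats infeasibility as a normal terminal state. The solver is validated in
the test suite against brute-force enumeration of all basic solutions on
random \(3 \times 8\) and \(4 \times 10\) instances (agreement to
\(10^{-8}\) on every instance).

## Why one LP cannot rank voxels, and what the recursion does

An optimal vertex has at most \(N\) nonzero weights. Voxels inside a
coherent anatomical cluster are nearly collinear, so the vertex names only
a few arbitrary representatives per cluster and a rerun may name different
ones. Ranking 20,000 voxels from single solutions therefore over-prunes
clusters — the selection is unstable exactly where the signal is strongest.

`recursive_select()` addresses this with two ingredients per round:

1. **Subsample aggregation.** The LP is solved `n_solves` times (default
   12) on random class-stratified subject subsamples (`subsample = 0.5` of
   each class). Each voxel accumulates its primal importance, the mean
   |w| across solves.
2. **Dual attractiveness.** Each optimal solve also prices every column:
   \(|a_j^\top y^*|\) equals 1 exactly on the support and approaches 1 for
   columns the vertex could have used at almost no extra cost — i.e. the
   near-duplicates inside a cluster that the primal solution arbitrarily
   excludes. The mean of this dual score over the solves is the round's
   primary ranking key; the primal importance is secondary, and |t| breaks
   only exact ties.

Each round appends the `batch_size` top-ranked voxels (default 200) to the
global order, removes them, and re-solves. Removal is what surfaces the
covariance component: once the strongly declining clusters are consumed,
the program must reconstruct the label vector from what remains, and
voxels whose only value is cancelling shared fluctuations of previously
selected clusters — or carrying a weak signal of their own — price up and
are selected next. When the remaining column count drops below the
subsample row count the equality system can no longer be satisfied, and
all remaining voxels are appended in decreasing |t| order.

The ordering is converted to weights by `assign_batch_weights()`: with
\(B\) batches, batch \(b\) gets weight \((B - b + 1)/B\) — the ladder
1.00, 0.99, …, 0.01 when 20,000 voxels are taken 200 at a time.

Both aggregation keys are computed from the same solves, so the recursion
costs `n_solves` LPs per batch. The defaults (12 solves of half the
subjects) were chosen to keep a 10-fold run of a 200-subject, 4,000-voxel
cohort around five minutes on one core while giving every cluster member
several chances to be hit or priced; they are exposed in
`pipeline_params()`.

## Pipeline, cross-validation, and the consensus pattern

`run_fold()` performs, strictly inside the training subjects of a fold:
voxelwise pooled-variance t-scores → top-`filter_k` filter (default
20,000; ranking by |t|, since the direction rule is a convention —
configurable via `filter_top_k(use_abs=)`) → per-voxel standardization →
recursive L1 ordering → SVM training on the first `n_classify` voxels.
Held-out subjects are transformed with the training statistics only. The
equal-variance t is used (rather than Welch) as the classical VBM default;
zero-variance voxels score 0, as constant columns carry no signal.

`run_cv()` pools the held-out predictions of all `M = 10` folds into
overall GR/SS/SC and intersects the fold-wise voxel sets:
`consensus_pattern()` keeps the voxels weighted in *all* folds, scores
them by the mean of their per-fold weights (the only reading consistent
with averaging the fold weightings into a final weighting), and returns
the top 1,000 as the final spatial pattern. The intersection is what
repairs the over-pruning instability: representative voxels differ fold to
fold, but cluster membership does not. `apply_pattern()` carries a frozen
pattern to a second cohort and cross-validates there (leave-one-out by
default, the appropriate choice for small validation cohorts);
standardization and classifier training are redone inside each validation
fold, so only the voxel set transfers.

Classification is a soft-margin linear SVM (e1071/libsvm, `C = 1`,
decision threshold fixed at 0, young = positive class). Linear is the only
kernel compatible with reporting voxel weights, and nothing is tuned. The
decision score is the signed distance surrogate \(w \cdot x + b\);
`score_age_correlation()` reports its Pearson correlation with
chronological age.

## The synthetic cohort generator

`generate_cohort()` draws cohorts that emulate the *output* of a VBM
preprocessing chain (segmentation, normalization, 8-mm smoothing are out
of scope — the generator produces what they would hand to the pipeline):

\[
x_{ij} = \text{baseline} + \beta_j \,\text{age}_i + \lambda_j z_i +
\epsilon_{ij},
\]

with ages uniform in 18–30 (young) and 50–91 (old), baseline density 1,
white noise of sd `noise_sd = 0.05` smoothed by a Gaussian of FWHM
`smooth_fwhm_voxels = 2` (\(\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})\),
reflective boundaries, mass-preserving), and planted spherical clusters:

* **direct** clusters with \(\beta_j = -0.01\) density/yr (the standard
  layout plants three of 40 voxels each on a 20×20×10 grid);
* **covarying** clusters with a ten-fold weaker marginal slope
  (\(\beta_j = -0.001\)) and a loading \(\lambda_j = 0.1\) on a latent
  factor \(z_i \sim N(0, \texttt{latent\_sd}^2)\) shared with their
  partnered direct cluster.

Design choices worth stating:

* **Smoothing is applied to the noise only**, so planted slopes remain
  exactly interpretable in recovery tests (a slope fitted on a cluster
  voxel estimates \(\beta_j\), not a blurred mixture).
* **The latent factor is shared pairwise**, one \(z\) per direct/covarying
  pair, producing exactly the single-voxel-vs-pair synergy without
  inducing global correlation.
* **`latent_sd = 2` by default**, so with loading 0.1 the latent
  fluctuation (sd 0.2) dominates the within-group density variation of a
  partnered voxel. This puts representative single-voxel accuracies in the
  80–90% band — the regime in which adding the weak partner voxel visibly
  raises the pair accuracy — while leaving covarying voxels marginally
  weak (|t| near the noise tail).
* **Ages are uniform** within each range; the generator stays
  parameter-light and cohort means/SDs are checked only loosely.

What the generator does *not* emulate: cortical anatomy, registration or
partial-volume artifacts, non-Gaussian intensity distributions, and any
spatial structure in the signal beyond spherical clusters. Passing tests
show the pipeline recovers planted linear-in-age and covariance structure
at realistic noise levels; they do not certify performance on real scanner
data.

## Numerical and degenerate-input conventions

* Voxel flat indices are 1-based, column-major over the grid (native R
  array order); one stated convention prevents cross-module off-by-ones.
* Standardization uses training-fold statistics everywhere; constant
  columns get scale 1 and map to zero.
* Ranking ties anywhere (equal |t|, equal importance) break by ascending
  voxel index, making every ordering deterministic.
* A cluster regression with a perfect fit (zero residual variance) returns
  p = 0 for a nonzero slope and p = 1 for a zero slope instead of NaN.
* `make_mask()` uses a mean-density threshold of 0.1 as a stand-in for the
  implicit masking of segmentation pipelines; real analyses typically
  supply their own mask.
* Every stochastic step (cohort generation, fold assignment, subsample
  draws) takes an explicit integer seed, and identical seeds reproduce
  results byte for byte.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the pipeline end to end
on the standard synthetic layout: 200 subjects (100 + 100) on a 20×20×10
grid (4,000 mask voxels), three direct clusters of 40 voxels, ten-fold
cross-validation with 50-voxel batches, and — for the covariance checks —
one additional covarying cluster. Unit tests use smaller cohorts (tens of
subjects, hundreds of voxels) built by the same generator. LP-oracle
equivalence is checked at 3×8 and 4×10, where enumeration of all basic
solutions is exact and fast.

## Known limitations

* Only binary cohort labels are supported as the sparse-representation
  target; continuous age as the target is out of scope.
* The t-filter is a ranking device; no multiple-testing correction is
  applied or intended.
* The simplex is dense; it is sized for hundreds of subjects by tens of
  thousands of voxels, not for millions of columns.
* Anatomical labeling (atlas regions, MNI coordinates of named structures)
  is out of scope; cluster reports are geometric.
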