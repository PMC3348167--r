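# sparsevbm

Sparse-representation MVPA for voxel-based morphometry of brain aging.

## What problem this solves

Gray-matter density maps from structural MRI show two kinds of age effect.
Some regions decline strongly and directly with age — any voxelwise
two-sample t-test finds them. Others barely change on their own, but their
volume co-fluctuates with that of strongly declining regions, so *pairs or
bundles* of voxels discriminate young from old far better than any member
alone. Univariate screening is blind to this second, covariance-borne
component.

`sparsevbm` implements a multivariate pipeline that recovers both. For a
cohort of N subjects with V mask voxels, let A be the N×V matrix of
(standardized) GM densities and y ∈ {+1, −1}^N the cohort labels
(+1 young, −1 old). The core step is the basis-pursuit program

```
min ‖w‖₁   subject to   A w = y,
```

the linear-programming relaxation of finding the sparsest exact
representation of the labels by voxel columns (solved via the non-negative
split w = u − v by a two-phase revised simplex shipped in `src/`). A
recursive procedure turns this into a full voxel ordering: each round
solves the program on several subject subsamples, ranks voxels by their
mean dual price |aⱼᵀy*| (1 on the support, ≈1 for near-duplicates the
optimal vertex happened to exclude) and mean |w|, selects a batch, removes
it, and re-solves — so that once the dominant clusters are consumed, voxels
that matter only through covariation are surfaced next. Batch b of B gets
weight (B−b+1)/B, the ladder 1.00, 0.99, …, 0.01 for 20,000 voxels in
batches of 200.

Selection runs inside each of M = 10 cross-validation folds (after a
two-sample-t filter keeping the top 20,000 voxels); the voxels surviving in
*all* folds, ranked by mean fold weight, form the consensus aging pattern
(default 1,000 voxels). A linear SVM reports GR/SS/SC (overall accuracy,
correct-young rate, correct-old rate), and cluster-level reports fit mean
cluster volume against age. A synthetic-cohort generator with planted
direct and covarying clusters provides ground truth for all of it.

Intended users: neuroimaging methods developers and anyone who wants a
self-contained, testable implementation of L1-minimisation voxel selection
with honest cross-validation hygiene.

## Worked example

Generate the standard synthetic cohort (200 subjects on a 20×20×10 grid:
three directly declining 40-voxel clusters plus one covarying cluster
partnered to the first), run the ten-fold cross-validated pipeline, and
inspect the result. The full run takes about six minutes on one core.

```r
library(sparsevbm)

spec <- synthetic_spec(clusters = default_aging_clusters(covarying = TRUE),
                       seed = 5)
gen <- generate_cohort(spec)
co  <- gen$cohort
co
#> vbm_cohort: 200 subjects (100 young, 100 old), 4000 voxels, ages 18-91

pars <- pipeline_params(batch_size = 50, n_classify = 200, pattern_size = 1000)
cv <- run_cv(co, pars, M = 10, seed = 21)
cv
#> cv_result: 10 folds | pooled GR 100.0%, SS 100.0%, SC 100.0% | pattern 1000 voxels

# the planted clusters dominate the head of the consensus pattern
planted <- unlist(gen$truth$cluster_cols)   # 160 voxels
mean(planted %in% cv$consensus$voxels[1:160])
#> [1] 0.98125

# the covarying cluster ranks far better under sparse selection than under |t|
tsc <- voxelwise_tscore(co)
rv  <- filter_top_k(tsc, ncol(co$X))
mean(match(gen$truth$cluster_cols$covary1, rv$order))          # |t| rank
#> [1] 446.25
bw  <- recursive_select(standardize_apply(co$X[, rv$order],
                                          standardize_fit(co$X[, rv$order])),
                        co$labels, batch_size = 50, tscores = rv$scores,
                        seed = 1)
mean(match(gen$truth$cluster_cols$covary1, rv$order[bw$order]))  # sparse rank
#> [1] 156.275

# per-cluster mean-volume-vs-age regression recovers the planted slope
r <- cluster_age_regression(co, gen$truth$cluster_cols$direct1)
c(slope = r$slope_b, se = r$slope_se, p = r$slope_p)
#>         slope            se             p
#> -1.023942e-02  5.702367e-04  2.020188e-43

# a weak voxel raises accuracy only through covariation with a strong one
d1 <- gen$truth$cluster_cols$direct1; cv1 <- gen$truth$cluster_cols$covary1
pw <- pairwise_voxel_discrimination(co, d1[which.max(abs(tsc[d1]))],
                                    cv1[which.max(abs(tsc[cv1]))],
                                    make_folds(co$labels, 10, seed = 2))
c(direct = pw$acc_a, covarying = pw$acc_b, pair = pw$acc_pair)
#>    direct covarying      pair
#>      0.86     0.565      1.00
```

Reading the output: the planted decline (−0.01 density/yr against noise sd
0.05) separates the cohorts, so the pooled generalization rate is 100% and
98% of the 160 planted voxels head the consensus pattern. The covarying
cluster — mid-field for the t-test (mean rank 446 of 4,000) — is pulled to
mean rank 156 by the sparse recursion, because once the directly declining
clusters are consumed the program needs it to cancel their shared latent
fluctuation. The same mechanism shows up per voxel: the best covarying
voxel alone barely beats chance (56.5%), yet paired with a strong direct
voxel it lifts accuracy from 86% to 100%. The fitted cluster slope
recovers the planted −0.01 within one standard error.

The methods vignette (`vignettes/sparse-aging-patterns.Rmd`) documents the
model, the solver, the recursion design, the generator, and their
limitations. A thin command-line front end over the same functions lives
in `inst/cli/sparsevbm.R` (`simulate`, `select`, `classify` subcommands on
YAML configs, NIfTI volumes and TSV subject tables).

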