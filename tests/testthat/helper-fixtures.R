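# Fixtures are built in code at test time; nothing is read from disk.

# Brute-force oracle for the minimum-1-norm exact representation: enumerate
# every square column subset (basic solutions) and take the feasible minimum.
enum_min_l1 <- function(A, y, tol = 1e-9) {
  m <- nrow(A)
  best <- Inf
  for (cols in utils::combn(ncol(A), m, simplify = FALSE)) {
    B <- A[, cols, drop = FALSE]
    if (abs(det(B)) < tol) next
    w <- solve(B, y)
    best <- min(best, sum(abs(w)))
  }
  best
}

# Small cohort with a handful of strongly label-aligned voxels in a sea of
# noise; separable by construction.
make_planted_cohort <- function(n_per_group = 10L, n_signal = 3L,
                                n_noise = 50L, signal_noise = 0.01,
                                seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_group
  y <- rep(c(1L, -1L), each = n_per_group)
  V <- n_signal + n_noise
  X <- matrix(rnorm(n * V), n, V)
  for (j in seq_len(n_signal)) {
    X[, j] <- y + rnorm(n, 0, signal_noise)
  }
  d <- c(V, 1L, 1L)
  while (prod(d) < V) d[1L] <- d[1L] + 1L
  in_mask <- array(FALSE, c(V, 1L, 1L))
  in_mask[seq_len(V)] <- TRUE
  ages <- ifelse(y == 1L, runif(n, 18, 30), runif(n, 50, 91))
  vbm_cohort(X, ages, y, brain_mask(in_mask))
}

# Small 3-D synthetic cohort with one strong planted cluster; near-noiseless
# so every fold separates perfectly.
make_separable_cohort <- function(seed = 7L) {
  spec <- synthetic_spec(
    grid_shape = c(8L, 8L, 6L), n_young = 20L, n_old = 20L,
    noise_sd = 1e-4, smooth_fwhm_voxels = 0,
    clusters = list(cluster_spec("c1", c(4L, 4L, 3L), "direct", -0.01,
                                 n_voxels = 12L)),
    seed = seed
  )
  generate_cohort(spec)
}

# Mid-size planted cohort for pipeline-level properties (kept small enough
# that a full cross-validated run stays in seconds).
make_midsize_cohort <- function(seed = 5L, covarying = FALSE) {
  clusters <- list(
    cluster_spec("direct1", c(4L, 4L, 3L), "direct", -0.01, n_voxels = 15L,
                 factor_loading = if (covarying) 0.1 else 0),
    cluster_spec("direct2", c(10L, 4L, 3L), "direct", -0.01, n_voxels = 15L)
  )
  if (covarying) {
    clusters <- c(clusters, list(
      cluster_spec("covary1", c(4L, 10L, 3L), "covarying", -0.001,
                   n_voxels = 15L, factor_loading = 0.1,
                   partner = "direct1")
    ))
  }
  spec <- synthetic_spec(grid_shape = c(14L, 14L, 6L), n_young = 30L,
                         n_old = 30L, noise_sd = 0.05,
                         smooth_fwhm_voxels = 2, clusters = clusters,
                         seed = seed)
  generate_cohort(spec)
}

# Study-condition cohorts used by the acceptance suite: 200 subjects on a
# 20x20x10 grid (4,000 mask voxels), three direct clusters of 40 voxels with
# slope -0.01 density/yr, noise sd 0.05, smoothing FWHM 2 voxels; optionally
# one covarying cluster (loading 0.1, slope -0.001) partnered to the first
# direct cluster.
make_study_cohort <- function(seed, covarying = FALSE) {
  generate_cohort(synthetic_spec(
    clusters = default_aging_clusters(covarying = covarying), seed = seed))
}
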