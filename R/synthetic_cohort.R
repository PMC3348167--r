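#' Gaussian smoothing of a 3-D field
#'
#' Separable isotropic Gaussian smoothing with kernel width given as
#' full-width-at-half-maximum in voxel units
#' (\eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}), mirroring the
#' preprocessing smoothing that gray-matter density maps receive. Boundaries
#' are handled by half-sample symmetric reflection, which preserves the total
#' sum of the field; `fwhm_voxels = 0` is the identity.
#'
#' @param volume numeric 3-D array.
#' @param fwhm_voxels kernel FWHM in voxels (>= 0).
#' @return The smoothed array, same dimensions.
#' @export
smooth_field <- function(volume, fwhm_voxels) {
  if (fwhm_voxels < 0) stop("'fwhm_voxels' must be >= 0")
  stopifnot(length(dim(volume)) == 3L)
  if (fwhm_voxels == 0) return(volume)
  sigma <- fwhm_voxels / (2 * sqrt(2 * log(2)))
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  kern <- exp(-(seq.int(-h, h))^2 / (2 * sigma^2))
  kern <- kern / sum(kern)

  conv_mat <- function(n) {
    C <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (t in seq.int(-h, h)) {
        j <- i + t
        while (j < 1L || j > n) {
          if (j < 1L) j <- 1L - j
          if (j > n) j <- 2L * n + 1L - j
        }
        C[i, j] <- C[i, j] + kern[t + h + 1L]
      }
    }
    C
  }

  v <- volume
  for (ax in 1:3) {
    d <- dim(v)
    others <- setdiff(1:3, ax)
    p <- aperm(v, c(ax, others))
    m <- conv_mat(d[ax]) %*% matrix(p, nrow = d[ax])
    v <- aperm(array(m, dim = c(d[ax], d[others])), order(c(ax, others)))
  }
  v
}

#' Planted cluster specification
#'
#' Describes one spherical cluster planted into a synthetic cohort. A
#' `direct` cluster declines linearly with age at `age_slope` density units
#' per year. A `covarying` cluster has (typically) a weak marginal age slope
#' but loads on a latent factor shared with the direct cluster named by
#' `partner`, so that the pair is jointly far more discriminative than either
#' cluster alone. Cluster extent is given either as a `radius` (all voxels
#' within it) or as `n_voxels` (that many nearest voxels to the center).
#'
#' @param id character cluster identifier.
#' @param center integer 3-vector, 1-based grid coordinates.
#' @param kind `"direct"` or `"covarying"`.
#' @param age_slope density units per year (negative = decline).
#' @param radius sphere radius in voxels (>= 1), or `NULL`.
#' @param n_voxels exact voxel count, or `NULL` (exactly one of `radius`,
#'   `n_voxels` must be given).
#' @param factor_loading coefficient on the shared latent factor (0 for a
#'   pure direct cluster).
#' @param partner id of the direct cluster sharing the latent factor
#'   (required for covarying clusters).
#' @return An object of class `cluster_spec`.
#' @export
cluster_spec <- function(id, center, kind = c("direct", "covarying"),
                         age_slope, radius = NULL, n_voxels = NULL,
                         factor_loading = 0, partner = NULL) {
  kind <- match.arg(kind)
  if (is.null(radius) == is.null(n_voxels)) {
    stop("give exactly one of 'radius' or 'n_voxels'")
  }
  if (!is.null(radius) && radius < 1) stop("'radius' must be >= 1")
  if (!is.null(n_voxels) && n_voxels < 1) stop("'n_voxels' must be >= 1")
  if (kind == "covarying" && is.null(partner)) {
    stop("a covarying cluster must name its direct 'partner'")
  }
  structure(
    list(id = as.character(id), center = as.integer(center), kind = kind,
         age_slope = age_slope, radius = radius, n_voxels = n_voxels,
         factor_loading = factor_loading, partner = partner),
    class = "cluster_spec"
  )
}

#' Voxel columns covered by a cluster specification
#'
#' Resolves a [cluster_spec()] to the flat (full-grid, column-major) voxel
#' columns it covers; errors when the covering sphere is clipped by the
#' grid boundary.
#'
#' @param cl a [cluster_spec()].
#' @param grid_shape integer 3-vector of voxel counts.
#' @return Sorted integer vector of voxel columns.
#' @export
cluster_cols <- function(cl, grid_shape) {
  co <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  d2 <- colSums((t(co) - cl$center)^2)
  if (!is.null(cl$radius)) {
    r <- cl$radius
    sel <- which(d2 <= r^2)
  } else {
    ord <- order(d2, seq_along(d2))
    sel <- sort(ord[seq_len(cl$n_voxels)])
    r <- sqrt(max(d2[sel]))
  }
  if (any(cl$center - r < 1) || any(cl$center + r > grid_shape)) {
    stop(sprintf("cluster '%s' extends outside the grid", cl$id))
  }
  sel
}

#' Synthetic cohort specification
#'
#' Parameters of the synthetic gray-matter cohort generator. Defaults follow
#' the cohort structure the pipeline targets: young subjects aged 18-30 and
#' old subjects aged 50-91 (ages uniform within range), a baseline density of
#' 1, white voxel noise of sd `noise_sd` smoothed with a Gaussian of FWHM
#' `smooth_fwhm_voxels` (smoothing is applied to the noise only, so planted
#' slopes stay exactly interpretable), and a latent factor of sd `latent_sd`
#' shared within each direct/covarying cluster pair.
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param n_young,n_old subject counts per cohort (>= 2 each).
#' @param young_age_range,old_age_range age ranges in years (must not
#'   overlap).
#' @param baseline_density density at age 0 for background voxels.
#' @param noise_sd sd of the white noise field before smoothing (> 0).
#' @param latent_sd sd of each shared latent factor.
#' @param smooth_fwhm_voxels noise smoothing FWHM in voxels.
#' @param clusters list of [cluster_spec()] objects; spheres must be disjoint
#'   and covarying partners must exist.
#' @param seed integer seed; identical specs generate identical cohorts.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(grid_shape = c(20L, 20L, 10L),
                           n_young = 100L, n_old = 100L,
                           young_age_range = c(18, 30),
                           old_age_range = c(50, 91),
                           baseline_density = 1,
                           noise_sd = 0.05,
                           latent_sd = 2,
                           smooth_fwhm_voxels = 2,
                           clusters = list(),
                           seed = 1L) {
  if (n_young < 2L || n_old < 2L) stop("need at least 2 subjects per cohort")
  if (max(young_age_range) >= min(old_age_range)) {
    stop("age ranges must not overlap")
  }
  if (noise_sd <= 0) stop("'noise_sd' must be > 0")
  ids <- vapply(clusters, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("cluster ids must be unique")
  vox <- lapply(clusters, cluster_cols, grid_shape = grid_shape)
  if (length(vox) > 1L) {
    all_v <- unlist(vox)
    if (anyDuplicated(all_v)) stop("planted clusters overlap")
  }
  for (cl in clusters) {
    if (cl$kind == "covarying") {
      p <- which(ids == cl$partner)
      if (length(p) != 1L || clusters[[p]]$kind != "direct") {
        stop(sprintf("covarying cluster '%s' needs an existing direct partner",
                     cl$id))
      }
    }
  }
  structure(
    list(grid_shape = as.integer(grid_shape), n_young = as.integer(n_young),
         n_old = as.integer(n_old), young_age_range = young_age_range,
         old_age_range = old_age_range, baseline_density = baseline_density,
         noise_sd = noise_sd, latent_sd = latent_sd,
         smooth_fwhm_voxels = smooth_fwhm_voxels, clusters = clusters,
         cluster_cols = vox, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Standard planted-cluster layout
#'
#' Three direct age-declining clusters of 40 voxels each (slope -0.01
#' density/year) on the default 20x20x10 grid; with `covarying = TRUE` a
#' fourth 40-voxel cluster is added whose marginal slope is ten times weaker
#' (-0.001) but which shares a latent factor (loading 0.1) with the first
#' direct cluster, reproducing the regime in which a voxel pair separates the
#' cohorts far better than either voxel alone.
#'
#' @param covarying add the covarying cluster and give its direct partner the
#'   same latent loading.
#' @return A list of [cluster_spec()] objects.
#' @export
default_aging_clusters <- function(covarying = FALSE) {
  loading1 <- if (covarying) 0.1 else 0
  cl <- list(
    cluster_spec("direct1", c(5L, 5L, 5L), "direct", -0.01, n_voxels = 40L,
                 factor_loading = loading1),
    cluster_spec("direct2", c(14L, 5L, 5L), "direct", -0.01, n_voxels = 40L),
    cluster_spec("direct3", c(10L, 14L, 5L), "direct", -0.01, n_voxels = 40L)
  )
  if (covarying) {
    cl <- c(cl, list(
      cluster_spec("covary1", c(5L, 14L, 5L), "covarying", -0.001,
                   n_voxels = 40L, factor_loading = 0.1, partner = "direct1")
    ))
  }
  cl
}

#' Generate a synthetic gray-matter cohort with ground truth
#'
#' Draws a cohort according to a [synthetic_spec()]. Voxel `j` of subject `i`
#' is \eqn{x_{ij} = \mathrm{baseline} + \beta_j \cdot \mathrm{age}_i +
#' \lambda_j z_{i} + \epsilon_{ij}}, where \eqn{\beta_j} and \eqn{\lambda_j}
#' are the planted slope and latent loading of the cluster containing voxel
#' `j` (0 in the background), \eqn{z_i} is the latent factor shared within
#' the voxel's cluster pair, and \eqn{\epsilon} is spatially smoothed white
#' noise. The mask covers the full grid.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `cohort` (a [vbm_cohort()]) and `truth`
#'   (class `vbm_ground_truth`: per-cluster voxel columns, per-voxel true
#'   slope and loading, latent factor values, cluster table).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n <- spec$n_young + spec$n_old
  V <- prod(spec$grid_shape)
  ages <- c(runif(spec$n_young, spec$young_age_range[1], spec$young_age_range[2]),
            runif(spec$n_old, spec$old_age_range[1], spec$old_age_range[2]))
  labels <- rep(c(1L, -1L), c(spec$n_young, spec$n_old))

  slope <- numeric(V)
  loading <- numeric(V)
  factor_of_voxel <- character(V)
  ids <- vapply(spec$clusters, `[[`, "", "id")
  for (k in seq_along(spec$clusters)) {
    cl <- spec$clusters[[k]]
    cols <- spec$cluster_cols[[k]]
    slope[cols] <- cl$age_slope
    if (cl$factor_loading != 0) {
      loading[cols] <- cl$factor_loading
      factor_of_voxel[cols] <- if (cl$kind == "covarying") cl$partner else cl$id
    }
  }
  factor_ids <- sort(unique(factor_of_voxel[factor_of_voxel != ""]))
  z <- matrix(0, n, length(factor_ids),
              dimnames = list(NULL, if (length(factor_ids)) factor_ids))
  if (length(factor_ids) > 0L) {
    z[] <- rnorm(n * length(factor_ids), 0, spec$latent_sd)
  }
  zv <- matrix(0, n, V)  # latent contribution per subject x voxel
  for (f in factor_ids) {
    cols <- which(factor_of_voxel == f)
    zv[, cols] <- outer(z[, f], loading[cols])
  }

  X <- matrix(0, n, V)
  for (i in seq_len(n)) {
    eps <- array(rnorm(V, 0, spec$noise_sd), spec$grid_shape)
    if (spec$smooth_fwhm_voxels > 0) {
      eps <- smooth_field(eps, spec$smooth_fwhm_voxels)
    }
    X[i, ] <- spec$baseline_density + slope * ages[i] + zv[i, ] +
      as.numeric(eps)
  }

  mask <- brain_mask(array(TRUE, spec$grid_shape))
  cohort <- vbm_cohort(X, ages, labels, mask)
  cluster_table <- data.frame(
    id = ids,
    kind = vapply(spec$clusters, `[[`, "", "kind"),
    size = lengths(spec$cluster_cols),
    age_slope = vapply(spec$clusters, `[[`, 0, "age_slope"),
    factor_loading = vapply(spec$clusters, `[[`, 0, "factor_loading"),
    stringsAsFactors = FALSE
  )
  truth <- structure(
    list(cluster_cols = stats::setNames(spec$cluster_cols, ids),
         true_slope = slope, loading = loading, latent = z,
         clusters = cluster_table),
    class = "vbm_ground_truth"
  )
  list(cohort = cohort, truth = truth)
}
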