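#' Connected clusters of a consensus pattern
#'
#' Connected components of the pattern's 3-D voxel set under 6-, 18- or
#' 26-connectivity (26 is the convention for voxel-based morphometry cluster
#' reporting), sorted by size descending. Geometry only; attach regression
#' results with [cluster_age_regression()].
#'
#' @param pattern a [consensus_pattern()] (or an integer vector of voxel
#'   columns).
#' @param mask a [brain_mask()].
#' @param connectivity 6, 18 or 26.
#' @return A list of `cluster_summary` objects: `cluster_id`, `voxels`
#'   (columns), `size`, `centroid` (grid coordinates), `representative`
#'   (voxel of peak mean consensus weight, when weights are available).
#' @export
connected_clusters <- function(pattern, mask, connectivity = 26L) {
  if (inherits(pattern, "consensus_pattern")) {
    voxels <- pattern$voxels
    weights <- pattern$mean_weight
  } else {
    voxels <- as.integer(pattern)
    weights <- NULL
  }
  if (length(voxels) == 0L) stop("empty pattern")
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  co <- mask_coords(mask, voxels)

  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nd <- rowSums(abs(off))
  off <- off[nd > 0 & nd <= switch(as.character(connectivity),
                                   "6" = 1L, "18" = 2L, "26" = 3L), ,
             drop = FALSE]

  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
  pos <- stats::setNames(seq_along(voxels), key(co))
  comp <- integer(length(voxels))
  cur <- 0L
  for (s in seq_along(voxels)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- sweep(off, 2L, unname(co[v, ]), "+")
      hit <- pos[key(nb)]
      hit <- hit[!is.na(hit)]
      new <- hit[comp[hit] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }

  clusters <- lapply(seq_len(cur), function(ci) {
    sel <- which(comp == ci)
    rep_vox <- if (!is.null(weights)) {
      sel_w <- weights[sel]
      voxels[sel][order(-sel_w, voxels[sel])][1L]
    } else {
      min(voxels[sel])
    }
    structure(list(cluster_id = ci, voxels = voxels[sel],
                   size = length(sel),
                   centroid = colMeans(co[sel, , drop = FALSE]),
                   representative = rep_vox),
              class = "cluster_summary")
  })
  sizes <- vapply(clusters, `[[`, 0L, "size")
  first_vox <- vapply(clusters, function(cl) min(cl$voxels), 0L)
  clusters <- clusters[order(-sizes, first_vox)]
  for (i in seq_along(clusters)) clusters[[i]]$cluster_id <- i
  clusters
}

#' Mean cluster volume regressed on age
#'
#' Ordinary least squares of per-subject mean density over the cluster's
#' voxels on chronological age (intercept included), with the two-sided t
#' test on the slope coefficient. A cluster `declines` when its slope is
#' negative and significant at `alpha`.
#'
#' @param cohort a [vbm_cohort()].
#' @param cluster a `cluster_summary` from [connected_clusters()] (or an
#'   integer vector of voxel columns).
#' @param alpha significance level for the slope test (default 0.05).
#' @return The cluster summary updated with `slope_b` (density units/year),
#'   `slope_se`, `slope_p`, `declines`, `mean_volume` (per subject).
#' @export
cluster_age_regression <- function(cohort, cluster, alpha = 0.05) {
  stopifnot(inherits(cohort, "vbm_cohort"))
  if (inherits(cluster, "cluster_summary")) {
    voxels <- cluster$voxels
  } else {
    voxels <- as.integer(cluster)
    cluster <- structure(list(cluster_id = NA_integer_, voxels = voxels,
                              size = length(voxels)),
                         class = "cluster_summary")
  }
  if (nrow(cohort$X) < 3L) stop("need at least 3 subjects")
  if (sd(cohort$ages) == 0) stop("zero age variance")
  mv <- rowMeans(cohort$X[, voxels, drop = FALSE])
  if (sd(mv) == 0) {
    # constant response: no decline and no evidence against the null
    cluster$slope_b <- 0
    cluster$slope_se <- 0
    cluster$slope_p <- 1
    cluster$declines <- FALSE
    cluster$mean_volume <- mv
    return(cluster)
  }
  fit <- lm(mv ~ age, data = data.frame(mv = mv, age = cohort$ages))
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are handled below
  cluster$slope_b <- sm["age", "Estimate"]
  cluster$slope_se <- sm["age", "Std. Error"]
  cluster$slope_p <- sm["age", "Pr(>|t|)"]
  if (!is.finite(cluster$slope_p)) {
    # perfect fit (zero residual variance): an exact nonzero line is
    # decisive, an exact constant carries no evidence of decline
    cluster$slope_p <- if (abs(cluster$slope_b) > 0) 0 else 1
  }
  cluster$declines <- (cluster$slope_b < 0) && (cluster$slope_p < alpha)
  cluster$mean_volume <- mv
  cluster
}

#' Cluster report table
#'
#' Runs [cluster_age_regression()] over every cluster and assembles the
#' standard report.
#'
#' @param cohort a [vbm_cohort()].
#' @param clusters list from [connected_clusters()].
#' @param alpha slope-test significance level.
#' @return Data frame with `cluster_id`, `size`, `centroid_x/y/z`,
#'   `slope_b`, `slope_se`, `p_value`, `declines`.
#' @export
cluster_report <- function(cohort, clusters, alpha = 0.05) {
  rows <- lapply(clusters, function(cl) {
    cl <- cluster_age_regression(cohort, cl, alpha)
    data.frame(cluster_id = cl$cluster_id, size = cl$size,
               centroid_x = cl$centroid[1L], centroid_y = cl$centroid[2L],
               centroid_z = cl$centroid[3L], slope_b = cl$slope_b,
               slope_se = cl$slope_se, p_value = cl$slope_p,
               declines = cl$declines)
  })
  do.call(rbind, rows)
}

#' Fraction of pattern voxels with lower old-group mean volume
#'
#' For each pattern voxel, compares the mean density of the old cohort with
#' that of the young cohort; reports the fraction that decreased (ties count
#' as non-decreasing).
#'
#' @param pattern a [consensus_pattern()] or integer vector of voxel columns.
#' @param cohort a [vbm_cohort()] containing both groups.
#' @return A list: `fraction` (in \[0, 1\], `NA` for an empty pattern),
#'   `n_decreased`, `n_voxels`.
#' @export
volume_change_fraction <- function(pattern, cohort) {
  stopifnot(inherits(cohort, "vbm_cohort"))
  voxels <- if (inherits(pattern, "consensus_pattern")) pattern$voxels
            else as.integer(pattern)
  if (length(voxels) == 0L) {
    warning("empty pattern: no voxels to compare")
    return(list(fraction = NA_real_, n_decreased = 0L, n_voxels = 0L))
  }
  young <- cohort$labels == 1L
  if (!any(young) || all(young)) stop("both groups must be present")
  m_young <- colMeans(cohort$X[young, voxels, drop = FALSE])
  m_old <- colMeans(cohort$X[!young, voxels, drop = FALSE])
  dec <- sum(m_old < m_young)
  list(fraction = dec / length(voxels), n_decreased = dec,
       n_voxels = length(voxels))
}

#' Discrimination of a single voxel versus a voxel pair
#'
#' Cross-validated generalization rate of the margin classifier using voxel
#' `a` alone, voxel `b` alone, and the pair — the check that a weakly
#' discriminative voxel can still raise accuracy through its covariation
#' with a strong one. Also returns the three full-data decision boundaries
#' for plotting.
#'
#' @param cohort a [vbm_cohort()].
#' @param voxel_a,voxel_b distinct voxel columns.
#' @param plan a [make_folds()] plan.
#' @param C SVM regularization constant.
#' @return A list: `acc_a`, `acc_b`, `acc_pair` (GR fractions) and
#'   `boundaries` (per feature set, the full-data `margin_model`).
#' @export
pairwise_voxel_discrimination <- function(cohort, voxel_a, voxel_b, plan,
                                          C = 1) {
  stopifnot(inherits(cohort, "vbm_cohort"), inherits(plan, "fold_plan"))
  if (voxel_a == voxel_b) stop("voxels must be distinct")
  V <- ncol(cohort$X)
  if (any(c(voxel_a, voxel_b) < 1L) || any(c(voxel_a, voxel_b) > V)) {
    stop("voxel index outside the mask")
  }
  sets <- list(a = voxel_a, b = voxel_b, pair = c(voxel_a, voxel_b))
  accs <- vapply(sets, function(cols) {
    pred <- integer(nrow(cohort$X))
    for (f in seq_len(plan$M)) {
      te <- which(plan$assignments == f)
      tr <- which(plan$assignments != f)
      Xtr <- cohort$X[tr, cols, drop = FALSE]
      std <- standardize_fit(Xtr)
      fit <- train_margin_classifier(standardize_apply(Xtr, std),
                                     cohort$labels[tr], C)
      pred[te] <- predict(fit, standardize_apply(
        cohort$X[te, cols, drop = FALSE], std))$label
    }
    confusion_and_metrics(cohort$labels, pred)$GR
  }, 0)
  boundaries <- lapply(sets, function(cols) {
    Xc <- cohort$X[, cols, drop = FALSE]
    std <- standardize_fit(Xc)
    train_margin_classifier(standardize_apply(Xc, std), cohort$labels, C)
  })
  list(acc_a = accs[["a"]], acc_b = accs[["b"]], acc_pair = accs[["pair"]],
       boundaries = boundaries)
}
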