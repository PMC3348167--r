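#' Voxelwise two-sample t statistic
#'
#' Classical pooled-variance (equal-variance) two-sample t per voxel, young
#' minus old. Voxels with zero pooled variance carry no discriminative signal
#' and are scored 0 (with a warning). Used as a ranking filter only; no
#' multiple-testing correction is applied or intended.
#'
#' @param cohort a [vbm_cohort()], or a numeric matrix (subjects x voxels).
#' @param labels +1/-1 labels; taken from the cohort when omitted.
#' @return Numeric vector of t values, one per voxel.
#' @export
voxelwise_tscore <- function(cohort, labels = NULL) {
  if (inherits(cohort, "vbm_cohort")) {
    X <- cohort$X
    if (is.null(labels)) labels <- cohort$labels
  } else {
    X <- as.matrix(cohort)
  }
  if (is.null(labels)) stop("'labels' required when 'cohort' is a matrix")
  y_idx <- labels == 1L
  n1 <- sum(y_idx)
  n2 <- sum(!y_idx)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 subjects")
  m1 <- colMeans(X[y_idx, , drop = FALSE])
  m2 <- colMeans(X[!y_idx, , drop = FALSE])
  v1 <- apply(X[y_idx, , drop = FALSE], 2L, var)
  v2 <- apply(X[!y_idx, , drop = FALSE], 2L, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  zero <- se == 0
  if (any(zero)) {
    warning(sprintf("%d voxel(s) with zero pooled variance scored t = 0",
                    sum(zero)))
    t[zero] <- 0
  }
  t
}

#' Ordered voxel set with per-voxel scores
#'
#' @param order integer vector of voxel columns, most informative first.
#' @param scores numeric scores aligned with `order`.
#' @param score_kind `"tscore"` or `"sparse_weight"`.
#' @return An object of class `ranked_voxels`.
#' @export
ranked_voxels <- function(order, scores, score_kind = c("tscore", "sparse_weight")) {
  score_kind <- match.arg(score_kind)
  order <- as.integer(order)
  if (anyDuplicated(order)) stop("duplicate voxel indices in ranking")
  if (length(order) != length(scores)) stop("'order' and 'scores' lengths differ")
  structure(list(order = order, scores = as.numeric(scores),
                 score_kind = score_kind),
            class = "ranked_voxels")
}

#' @export
print.ranked_voxels <- function(x, ...) {
  cat(sprintf("ranked_voxels: %d voxels by %s (top score %.4g)\n",
              length(x$order), x$score_kind, x$scores[1L]))
  invisible(x)
}

#' Retain the top-k voxels by absolute t score
#'
#' The first selection step: keep the `k` voxels with the largest |t|,
#' ordered by |t| descending (ties broken by ascending voxel index). The
#' conventional filter size for whole-brain maps is 20,000 voxels.
#'
#' @param tscores numeric vector of per-voxel t values.
#' @param k number of voxels to retain (1..V).
#' @param use_abs rank by |t| (default) rather than signed t.
#' @return A [ranked_voxels()] carrying the signed t scores of the retained
#'   voxels.
#' @export
filter_top_k <- function(tscores, k = 20000L, use_abs = TRUE) {
  V <- length(tscores)
  if (k < 1L || k > V) stop(sprintf("'k' must be in 1..%d", V))
  key <- if (use_abs) abs(tscores) else tscores
  ord <- order(-key, seq_len(V))
  sel <- ord[seq_len(k)]
  ranked_voxels(sel, tscores[sel], "tscore")
}

#' Export a ranking as a coordinate table
#'
#' @param ranking a [ranked_voxels()].
#' @param mask a [brain_mask()] resolving voxel columns to coordinates.
#' @return Data frame with `voxel_col`, `x`, `y`, `z`, `score`, `rank`.
#' @export
ranking_table <- function(ranking, mask) {
  co <- mask_coords(mask, ranking$order)
  data.frame(voxel_col = ranking$order, x = co[, 1L], y = co[, 2L],
             z = co[, 3L], score = ranking$scores,
             rank = seq_along(ranking$order))
}
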