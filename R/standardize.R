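#' Column standardization with training statistics
#'
#' L1-minimisation and margin classifiers are scale-sensitive, so every
#' voxel column is centred and scaled to unit variance using statistics from
#' the training subjects only; held-out subjects are transformed with the
#' same statistics. Constant columns get scale 1 so they map to zero rather
#' than NaN.
#'
#' @param X numeric training matrix (subjects x voxels).
#' @return `standardize_fit()`: a list with `center`, `scale`.
#' @export
standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

#' @param stats a fit from `standardize_fit()`.
#' @param cols optional column subset (indices into the fitted columns) to
#'   transform.
#' @rdname standardize_fit
#' @export
standardize_apply <- function(X, stats, cols = NULL) {
  if (is.null(cols)) {
    sweep(sweep(X, 2L, stats$center, "-"), 2L, stats$scale, "/")
  } else {
    sweep(sweep(X[, cols, drop = FALSE], 2L, stats$center[cols], "-"),
          2L, stats$scale[cols], "/")
  }
}
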