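#' Pipeline parameters
#'
#' Defaults follow the standard whole-brain configuration: t-filter of
#' 20,000 voxels, selection batches of 200, a 1,000-voxel consensus pattern,
#' ten folds and a linear SVM with C = 1. `n_solves` and `subsample` control
#' the per-round subsample aggregation of [recursive_select()].
#'
#' @param filter_k voxels retained by the t-filter (capped at V).
#' @param batch_size voxels selected per recursion round.
#' @param n_classify voxels used for per-fold classification.
#' @param pattern_size consensus pattern size.
#' @param C SVM regularization constant.
#' @param n_solves LP solves per recursion round.
#' @param subsample subject fraction per LP solve.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(filter_k = 20000L, batch_size = 200L,
                            n_classify = 1000L, pattern_size = 1000L,
                            C = 1, n_solves = 12L, subsample = 0.5) {
  structure(list(filter_k = as.integer(filter_k),
                 batch_size = as.integer(batch_size),
                 n_classify = as.integer(n_classify),
                 pattern_size = as.integer(pattern_size),
                 C = C, n_solves = as.integer(n_solves),
                 subsample = subsample),
            class = c("pipeline_params", "list"))
}

# deterministic per-fold seed derived from the plan seed (kept within
# 32-bit integer range)
fold_seed <- function(seed, fold) {
  as.integer((as.numeric(seed) * 131 + fold * 7919) %% 2147483629)
}

#' Stratified cross-validation fold plan
#'
#' Partitions subjects into `M` folds, stratified by class so fold sizes
#' within each class differ by at most one. `M = N` gives leave-one-out
#' cross-validation (each fold a singleton, stratification moot).
#'
#' @param labels +1/-1 labels.
#' @param M number of folds (2..N).
#' @param seed integer seed for the shuffle.
#' @param allow_unstratified permit classes smaller than `M` (fold sizes then
#'   balanced overall, not per class).
#' @return An object of class `fold_plan`: `M`, `assignments` (fold id per
#'   subject), `seed`.
#' @export
make_folds <- function(labels, M, seed = 1L, allow_unstratified = FALSE) {
  N <- length(labels)
  if (M < 2L || M > N) stop("'M' must be in 2..N")
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  assignments <- integer(N)
  if (M == N) {
    assignments <- seq_len(N)
  } else {
    classes <- sort(unique(labels), decreasing = TRUE)
    small <- vapply(classes, function(cl) sum(labels == cl) < M, TRUE)
    if (any(small) && !allow_unstratified) {
      stop("a class has fewer subjects than folds; ",
           "set allow_unstratified = TRUE to fold anyway")
    }
    if (any(small)) {
      assignments[sample.int(N)] <- rep_len(seq_len(M), N)
    } else {
      for (cl in classes) {
        idx <- which(labels == cl)
        assignments[idx[sample.int(length(idx))]] <-
          rep_len(seq_len(M), length(idx))
      }
    }
  }
  structure(list(M = as.integer(M), assignments = assignments,
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Run one cross-validation fold
#'
#' Voxel selection (t-filter, recursive L1 ordering), standardization and
#' classifier training use only the training subjects of the fold; held-out
#' subjects are transformed with the training statistics and scored.
#'
#' @param cohort a [vbm_cohort()].
#' @param plan a [make_folds()] plan.
#' @param fold_id fold to hold out (1..M).
#' @param params a [pipeline_params()] list.
#' @return A list: `fold_id`, `weighting` (a [assign_batch_weights()] object
#'   whose `order` holds global voxel columns), `metrics`
#'   ([confusion_and_metrics()] on the held-out part), `scores` (per held-out
#'   subject data frame), `test_idx`.
#' @export
run_fold <- function(cohort, plan, fold_id, params = pipeline_params()) {
  stopifnot(inherits(cohort, "vbm_cohort"), inherits(plan, "fold_plan"))
  if (!fold_id %in% seq_len(plan$M)) stop("invalid fold id")
  tr <- which(plan$assignments != fold_id)
  te <- which(plan$assignments == fold_id)
  y_tr <- cohort$labels[tr]

  tsc <- suppressWarnings(voxelwise_tscore(cohort$X[tr, , drop = FALSE], y_tr))
  k <- min(params$filter_k, ncol(cohort$X))
  rv <- filter_top_k(tsc, k)

  std <- standardize_fit(cohort$X[tr, rv$order, drop = FALSE])
  Xtr <- standardize_apply(cohort$X[tr, rv$order, drop = FALSE], std)
  bw <- recursive_select(Xtr, y_tr, batch_size = params$batch_size,
                         tscores = rv$scores, n_solves = params$n_solves,
                         subsample = params$subsample,
                         seed = fold_seed(plan$seed, fold_id))

  g_order <- rv$order[bw$order]  # local filtered indices -> global columns
  weighting <- bw
  weighting$order <- g_order

  n_cl <- min(params$n_classify, length(g_order))
  cols <- bw$order[seq_len(n_cl)]
  fit <- train_margin_classifier(Xtr[, cols, drop = FALSE], y_tr,
                                 C = params$C)
  Xte <- standardize_apply(cohort$X[te, rv$order, drop = FALSE], std)
  pr <- predict(fit, Xte[, cols, drop = FALSE])
  metrics <- confusion_and_metrics(cohort$labels[te], pr$label)
  scores <- data.frame(subject_id = cohort$subject_ids[te],
                       true_label = cohort$labels[te],
                       predicted_label = pr$label,
                       decision_score = pr$score)
  list(fold_id = fold_id, weighting = weighting, metrics = metrics,
       scores = scores, test_idx = te)
}

#' Consensus spatial pattern across folds
#'
#' Intersects the voxel sets weighted in every fold (a voxel must survive
#' the t-filter in all M folds), scores each surviving voxel by the mean of
#' its per-fold weights, and returns the `top_n` by mean weight — the final
#' fixed spatial pattern. Intersecting across folds counteracts the
#' instability of single sparse solutions, which pick different
#' representative voxels on reruns.
#'
#' @param fold_weightings list of per-fold [assign_batch_weights()] objects
#'   with global voxel columns in `$order`.
#' @param top_n pattern size (default 1000); all survivors are returned with
#'   a warning when fewer remain.
#' @param grid_shape optional grid recorded for downstream geometry checks.
#' @return An object of class `consensus_pattern`: `voxels` (ordered by
#'   decreasing mean weight, ties by ascending column), `mean_weight`,
#'   `fold_presence` (= M for every voxel), `M`, `grid_shape`.
#' @export
consensus_pattern <- function(fold_weightings, top_n = 1000L,
                              grid_shape = NULL) {
  M <- length(fold_weightings)
  if (M < 2L) stop("need at least 2 fold weightings")
  sets <- lapply(fold_weightings, `[[`, "order")
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) {
    warning("empty intersection across folds; returning an empty pattern")
    return(structure(list(voxels = integer(0), mean_weight = numeric(0),
                          fold_presence = integer(0), M = M,
                          grid_shape = grid_shape),
                     class = "consensus_pattern"))
  }
  wsum <- numeric(length(common))
  for (fw in fold_weightings) {
    wsum <- wsum + fw$weights[match(common, fw$order)]
  }
  mw <- wsum / M
  ord <- order(-mw, common)
  common <- common[ord]
  mw <- mw[ord]
  if (length(common) < top_n) {
    warning(sprintf("only %d voxels survive the intersection (requested %d)",
                    length(common), top_n))
  }
  keep <- seq_len(min(top_n, length(common)))
  structure(list(voxels = common[keep], mean_weight = mw[keep],
                 fold_presence = rep(M, length(keep)), M = M,
                 grid_shape = grid_shape),
            class = "consensus_pattern")
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat(sprintf("consensus_pattern: %d voxels from %d folds (mean weight %.3f..%.3f)\n",
              length(x$voxels), x$M,
              if (length(x$voxels)) x$mean_weight[1L] else NA,
              if (length(x$voxels)) x$mean_weight[length(x$voxels)] else NA))
  invisible(x)
}

#' Full cross-validated selection and classification run
#'
#' Runs every fold of the plan, pools the held-out predictions into overall
#' confusion metrics, and builds the consensus pattern from the per-fold
#' weightings.
#'
#' @param cohort a [vbm_cohort()].
#' @param params a [pipeline_params()] list.
#' @param M fold count (default 10).
#' @param seed fold plan seed.
#' @param plan optional pre-built [make_folds()] plan (overrides `M`/`seed`).
#' @return An object of class `cv_result`: `folds` (per-fold results),
#'   `pooled` (pooled [confusion_and_metrics()]), `consensus`
#'   (a [consensus_pattern()]), `plan`, `params`, `scores` (all held-out
#'   subject scores).
#' @export
run_cv <- function(cohort, params = pipeline_params(), M = 10L, seed = 1L,
                   plan = NULL) {
  stopifnot(inherits(cohort, "vbm_cohort"))
  if (is.null(plan)) plan <- make_folds(cohort$labels, M, seed)
  folds <- lapply(seq_len(plan$M), function(f)
    run_fold(cohort, plan, f, params))
  pred <- integer(nrow(cohort$X))
  for (fr in folds) pred[fr$test_idx] <- fr$scores$predicted_label
  pooled <- confusion_and_metrics(cohort$labels, pred)
  consensus <- consensus_pattern(lapply(folds, `[[`, "weighting"),
                                 top_n = params$pattern_size,
                                 grid_shape = cohort$mask$grid_shape)
  scores <- do.call(rbind, lapply(folds, `[[`, "scores"))
  structure(list(folds = folds, pooled = pooled, consensus = consensus,
                 plan = plan, params = params, scores = scores),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds | pooled GR %.1f%%, SS %.1f%%, SC %.1f%% | pattern %d voxels\n",
              x$plan$M, x$pooled$GR_pct, x$pooled$SS_pct, x$pooled$SC_pct,
              length(x$consensus$voxels)))
  invisible(x)
}

#' Apply a consensus pattern to a second cohort
#'
#' Classification restricted to the pattern voxels, cross-validated on the
#' second cohort: leave-one-out by default (the choice for small validation
#' cohorts), or any [make_folds()] plan. Standardization and training are
#' redone inside each fold; only the voxel set is carried over.
#'
#' @param pattern a [consensus_pattern()].
#' @param cohort2 a [vbm_cohort()] on the same grid.
#' @param C SVM regularization constant.
#' @param folds `"loocv"` or a [make_folds()] plan.
#' @return A list: `metrics` (pooled [confusion_and_metrics()]), `scores`
#'   (per-subject data frame with decision scores).
#' @export
apply_pattern <- function(pattern, cohort2, C = 1, folds = "loocv") {
  stopifnot(inherits(pattern, "consensus_pattern"),
            inherits(cohort2, "vbm_cohort"))
  if (length(pattern$voxels) == 0L) stop("empty pattern")
  if (!is.null(pattern$grid_shape) &&
      !identical(as.integer(pattern$grid_shape),
                 as.integer(cohort2$mask$grid_shape))) {
    stop("pattern grid does not match the cohort grid")
  }
  if (any(pattern$voxels > ncol(cohort2$X))) {
    stop("pattern voxel outside the cohort mask")
  }
  N <- nrow(cohort2$X)
  Xp <- cohort2$X[, pattern$voxels, drop = FALSE]
  if (identical(folds, "loocv")) {
    assignments <- seq_len(N)
    M <- N
  } else {
    stopifnot(inherits(folds, "fold_plan"))
    assignments <- folds$assignments
    M <- folds$M
  }
  pred <- integer(N)
  score <- numeric(N)
  for (f in seq_len(M)) {
    te <- which(assignments == f)
    tr <- setdiff(seq_len(N), te)
    std <- standardize_fit(Xp[tr, , drop = FALSE])
    fit <- train_margin_classifier(
      standardize_apply(Xp[tr, , drop = FALSE], std), cohort2$labels[tr], C)
    pr <- predict(fit, standardize_apply(Xp[te, , drop = FALSE], std))
    pred[te] <- pr$label
    score[te] <- pr$score
  }
  list(metrics = confusion_and_metrics(cohort2$labels, pred),
       scores = data.frame(subject_id = cohort2$subject_ids,
                           true_label = cohort2$labels,
                           predicted_label = pred,
                           decision_score = score))
}
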