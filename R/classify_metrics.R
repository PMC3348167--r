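#' Train a linear max-margin classifier
#'
#' Soft-margin linear support vector machine on the selected voxels (libsvm
#' via e1071). The decision score is \eqn{w \cdot x + b}; young subjects are
#' the positive class, and the decision threshold is fixed at 0. Columns are
#' expected to be standardized with training statistics.
#'
#' @param X numeric training matrix (subjects x selected voxels).
#' @param y +1/-1 labels (+1 = young).
#' @param C soft-margin regularization constant (default 1).
#' @return An object of class `margin_model` with fields `w`, `b`, `C`.
#' @export
train_margin_classifier <- function(X, y, C = 1) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1 or -1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    kernel = "linear", cost = C, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the score so that positive means young (+1)
  sc <- X %*% w + b
  pred_pos <- fit$fitted == "1"
  if (mean((sc > 0) == pred_pos) < 0.5) {
    w <- -w
    b <- -b
  }
  structure(list(w = w, b = b, C = C, n_features = ncol(X)),
            class = "margin_model")
}

#' @param object a `margin_model`.
#' @param newdata matrix with the same columns (and standardization) as the
#'   training matrix.
#' @param ... unused.
#' @return A list with `score` (decision values) and `label` (+1/-1).
#' @rdname train_margin_classifier
#' @export
predict.margin_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("newdata must have ", object$n_features, " columns")
  }
  score <- as.numeric(newdata %*% object$w + object$b)
  list(score = score, label = ifelse(score > 0, 1L, -1L))
}

#' Confusion counts and GR/SS/SC rates
#'
#' Counts with young as the positive class: TP young predicted young, FN
#' young predicted old, TN old predicted old, FP old predicted young. The
#' rates are the generalization rate GR = (TP+TN)/N (overall accuracy),
#' sensitivity SS = TP/(TP+FN) (correct young) and specificity
#' SC = TN/(TN+FP) (correct old). Percentages are reported at one decimal
#' with round-half-to-even.
#'
#' @param y_true,y_pred +1/-1 vectors of equal length.
#' @return An object of class `confusion_metrics` with fields `TP`, `FN`,
#'   `TN`, `FP`, `GR`, `SS`, `SC` (fractions) and `GR_pct`, `SS_pct`,
#'   `SC_pct` (one-decimal percentages).
#' @examples
#' m <- confusion_and_metrics(rep(c(1, -1), c(24, 32)),
#'                            rep(c(1, -1, -1, 1), c(23, 1, 31, 1)))
#' c(m$GR_pct, m$SS_pct, m$SC_pct)  # 96.4 95.8 96.8
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  if (length(y_true) == 0L) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% c(-1, 1))) stop("labels must be +1 or -1")
  TP <- sum(y_true == 1 & y_pred == 1)
  FN <- sum(y_true == 1 & y_pred == -1)
  TN <- sum(y_true == -1 & y_pred == -1)
  FP <- sum(y_true == -1 & y_pred == 1)
  confusion_from_counts(TP, FN, TN, FP)
}

#' @param TP,FN,TN,FP integer confusion counts (young = positive class).
#' @rdname confusion_and_metrics
#' @export
confusion_from_counts <- function(TP, FN, TN, FP) {
  N <- TP + FN + TN + FP
  if (N == 0L) stop("empty input")
  GR <- (TP + TN) / N
  SS <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  SC <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  structure(
    list(TP = TP, FN = FN, TN = TN, FP = FP, N = N,
         GR = GR, SS = SS, SC = SC,
         GR_pct = round(100 * GR, 1L), SS_pct = round(100 * SS, 1L),
         SC_pct = round(100 * SC, 1L)),
    class = "confusion_metrics"
  )
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion_metrics: N=%d TP=%d FN=%d TN=%d FP=%d | GR %.1f%%, SS %.1f%%, SC %.1f%%\n",
              x$N, x$TP, x$FN, x$TN, x$FP, x$GR_pct, x$SS_pct, x$SC_pct))
  invisible(x)
}

#' Pearson correlation between decision scores and age
#'
#' The decision score of the margin classifier is a signed distance from the
#' separating hyperplane; over a cohort it tracks chronological age, and this
#' reports their Pearson correlation.
#'
#' @param scores numeric decision values.
#' @param ages ages in years.
#' @return Pearson r in \[-1, 1\].
#' @export
score_age_correlation <- function(scores, ages) {
  if (length(scores) != length(ages)) stop("lengths differ")
  if (length(scores) < 3L) stop("need at least 3 subjects")
  if (sd(scores) == 0 || sd(ages) == 0) stop("zero variance input")
  cor(scores, ages)
}

#' Cross-validated accuracy as a function of voxel count
#'
#' For each entry of `n_grid`, classifies with the first `n` voxels of the
#' per-fold ranking (t-filter plus, for `method = "sparse"`, the recursive
#' L1 ordering), with the ranking recomputed inside each training fold, and
#' reports the pooled cross-validated generalization rate.
#'
#' @param cohort a [vbm_cohort()].
#' @param plan a [make_folds()] plan.
#' @param n_grid integer vector of voxel counts.
#' @param method `"sparse"` (t-filter then recursive L1 ordering) or
#'   `"ttest"` (|t| ordering alone).
#' @param params a [pipeline_params()] list.
#' @return Data frame with columns `n_voxels` and `GR`.
#' @export
accuracy_vs_nvoxels <- function(cohort, plan, n_grid,
                                method = c("sparse", "ttest"),
                                params = pipeline_params()) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "vbm_cohort"), inherits(plan, "fold_plan"))
  k_max <- min(params$filter_k, ncol(cohort$X))
  if (any(n_grid < 1L) || any(n_grid > k_max)) {
    stop(sprintf("'n_grid' must lie in 1..%d (the ranking length)", k_max))
  }
  pred <- matrix(NA_integer_, nrow(cohort$X), length(n_grid))
  for (fold in seq_len(plan$M)) {
    tr <- which(plan$assignments != fold)
    te <- which(plan$assignments == fold)
    tsc <- suppressWarnings(voxelwise_tscore(cohort$X[tr, , drop = FALSE],
                                             cohort$labels[tr]))
    rv <- filter_top_k(tsc, k_max)
    std <- standardize_fit(cohort$X[tr, rv$order, drop = FALSE])
    Xtr <- standardize_apply(cohort$X[tr, rv$order, drop = FALSE], std)
    Xte <- standardize_apply(cohort$X[te, rv$order, drop = FALSE], std)
    if (method == "sparse") {
      bw <- recursive_select(Xtr, cohort$labels[tr],
                             batch_size = params$batch_size,
                             tscores = rv$scores,
                             n_solves = params$n_solves,
                             subsample = params$subsample,
                             seed = fold_seed(plan$seed, fold))
      ord <- bw$order
    } else {
      ord <- seq_along(rv$order)
    }
    for (g in seq_along(n_grid)) {
      cols <- ord[seq_len(n_grid[g])]
      fit <- train_margin_classifier(Xtr[, cols, drop = FALSE],
                                     cohort$labels[tr], C = params$C)
      pred[te, g] <- predict(fit, Xte[, cols, drop = FALSE])$label
    }
  }
  data.frame(
    n_voxels = as.integer(n_grid),
    GR = vapply(seq_along(n_grid), function(g) {
      confusion_and_metrics(cohort$labels, pred[, g])$GR
    }, 0)
  )
}
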