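#' Minimum 1-norm representation of the label vector
#'
#' Solves the basis-pursuit problem
#' \deqn{\min_w \|w\|_1 \quad \text{s.t.} \quad A w = y,}
#' the convex relaxation of the sparsest exact representation of the cohort
#' labels by voxel columns. The split \eqn{w = u - v} with \eqn{u, v \ge 0}
#' turns it into a non-negative linear program, solved by a two-phase
#' revised simplex (so the returned solution is an exact vertex, with at
#' most one nonzero per constraint row).
#'
#' @param A numeric matrix (subjects x voxels), typically standardized
#'   columns.
#' @param y numeric vector of +1/-1 labels, one per row of A.
#' @param feas_tol feasibility tolerance on the equality constraints.
#' @param support_tol magnitude below which a weight is treated as zero.
#' @param max_iter simplex iteration cap.
#' @return An object of class `sparse_solution`: `w` (signed weights),
#'   `l1_norm`, `residual_inf` (max abs constraint violation), `support`
#'   (column indices with |w| > `support_tol`, decreasing |w|, ties by
#'   ascending index), `status` (`"optimal"` or `"infeasible"`), and `dual`
#'   (per-column attractiveness \eqn{|a_j^\top y^*|} under the optimal dual
#'   prices: exactly 1 on the support, near 1 for columns that are almost
#'   profitable — e.g. near-duplicates of support columns).
#'   Infeasibility is reported in the status, not raised as an error.
#' @examples
#' s <- solve_min_l1(rbind(c(1, 0), c(0, 1)), c(1, -1))
#' s$w        # 1, -1
#' s$l1_norm  # 2
#' @export
solve_min_l1 <- function(A, y, feas_tol = 1e-7, support_tol = 1e-8,
                         max_iter = 200000L) {
  A <- as.matrix(A)
  if (nrow(A) < 2L) stop("A needs at least 2 rows")
  if (ncol(A) < 1L) stop("A needs at least 1 column")
  if (length(y) != nrow(A)) stop("length of y must match rows of A")
  if (!all(y %in% c(-1, 1))) stop("y entries must be +1 or -1")
  res <- .bp_simplex_cpp(A, as.numeric(y), feas_tol, as.integer(max_iter))
  if (res$status == 1L) {
    return(structure(list(w = rep(0, ncol(A)), l1_norm = NA_real_,
                          residual_inf = NA_real_, support = integer(0),
                          status = "infeasible"),
                     class = "sparse_solution"))
  }
  if (res$status != 0L) {
    stop("simplex did not converge (solver status ", res$status, ")")
  }
  w <- as.numeric(res$w)
  supp <- which(abs(w) > support_tol)
  supp <- supp[order(-abs(w[supp]), supp)]
  structure(
    list(w = w, l1_norm = sum(abs(w)),
         residual_inf = max(abs(A %*% w - y)),
         support = supp, status = "optimal",
         dual = as.numeric(res$dual)),
    class = "sparse_solution"
  )
}

#' @export
print.sparse_solution <- function(x, ...) {
  if (x$status == "infeasible") {
    cat("sparse_solution: infeasible\n")
  } else {
    cat(sprintf("sparse_solution: |support| = %d, l1 = %.6g, residual = %.2g\n",
                length(x$support), x$l1_norm, x$residual_inf))
  }
  invisible(x)
}

#' Convert a selection order into batch weightings
#'
#' Voxels are weighted by the batch in which they were selected: with `B`
#' batches, batch `b` receives weight `(B - b + 1) / B`, the descending
#' ladder 1.00, 0.99, ..., 0.01 when 20,000 voxels are taken 200 at a time.
#' The last batch may be short.
#'
#' @param order integer vector, the global voxel selection order.
#' @param batch_size voxels per batch (default 200).
#' @return An object of class `batch_weighting`: `order`, `weights` (in
#'   (0, 1], constant within batch, non-increasing), `batch` (1-based batch
#'   per voxel), `batch_size`, `n_batches`.
#' @export
assign_batch_weights <- function(order, batch_size = 200L) {
  if (length(order) == 0L) stop("'order' must be non-empty")
  if (batch_size < 1L) stop("'batch_size' must be >= 1")
  L <- length(order)
  B <- ceiling(L / batch_size)
  batch <- ((seq_len(L) - 1L) %/% batch_size) + 1L
  structure(
    list(order = as.integer(order), weights = (B - batch + 1) / B,
         batch = batch, batch_size = as.integer(batch_size),
         n_batches = as.integer(B)),
    class = "batch_weighting"
  )
}

#' @export
print.batch_weighting <- function(x, ...) {
  cat(sprintf("batch_weighting: %d voxels in %d batches of %d (weights %.2f..%.2f)\n",
              length(x$order), x$n_batches, x$batch_size,
              x$weights[1L], x$weights[length(x$weights)]))
  invisible(x)
}

#' Recursive sparse-representation voxel selection
#'
#' Orders all (filtered) voxels by recursive L1-minimisation. Each round
#' selects `batch_size` voxels: the basis-pursuit program is solved on
#' several random class-stratified subject subsamples and each voxel is
#' scored by (1) its primal importance, the mean |w| across the solves, and
#' (2) its mean dual attractiveness \eqn{|a_j^\top y^*|}, which rates
#' columns the optimal vertex happened to exclude — near-duplicates of
#' support columns price close to 1. The round's top voxels (primal first,
#' dual as the secondary key, |t| only breaking exact ties) are appended to
#' the global order and removed before the next round. Once the LP can no
#' longer run — the remaining column count drops below the subsample row
#' count, so the equality system cannot be satisfied — every remaining voxel
#' is appended in decreasing |t| order.
#'
#' A single LP cannot rank near-collinear cluster voxels: its optimal vertex
#' names only a few representative columns per cluster and a rerun may name
#' different ones. Aggregating |w| over subject subsamples within each round
#' restores a stable per-voxel importance while keeping the recursive
#' structure (strong voxels are consumed first; once removed, later rounds
#' surface voxels that matter only through their covariation with others).
#'
#' @param X numeric matrix of training subjects x filtered voxels, columns
#'   standardized (see [standardize_fit()]).
#' @param y +1/-1 labels.
#' @param batch_size voxels selected per round (default 200).
#' @param tscores per-column |t| scores (or signed t; absolute values are
#'   used) for tie-breaking and fallback. Computed internally from `X`, `y`
#'   when omitted.
#' @param n_solves LP solves per round (default 12).
#' @param subsample fraction of subjects per solve (default 0.5, stratified
#'   by class).
#' @param seed integer seed for the subsample draws.
#' @param feas_tol,support_tol tolerances passed to [solve_min_l1()].
#' @param max_lp_rounds optional cap on LP rounds (later rounds fall back to
#'   |t| ordering); `Inf` by default.
#' @return A [assign_batch_weights()] object over all columns of `X`, with
#'   attribute `rounds` (per-round record: round, number of LP solves that
#'   converged, voxels selected).
#' @export
recursive_select <- function(X, y, batch_size = 200L, tscores = NULL,
                             n_solves = 12L, subsample = 0.5, seed = 1L,
                             feas_tol = 1e-7, support_tol = 1e-8,
                             max_lp_rounds = Inf) {
  X <- as.matrix(X)
  K <- ncol(X)
  n <- nrow(X)
  if (K < 1L) stop("X needs at least one column")
  if (batch_size < 1L) stop("'batch_size' must be >= 1")
  if (!all(y %in% c(-1, 1))) stop("y entries must be +1 or -1")
  if (is.null(tscores)) {
    tscores <- suppressWarnings(voxelwise_tscore(X, as.integer(y)))
  }
  tabs <- abs(tscores)
  if (length(tabs) != K) stop("'tscores' must have one value per column")

  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))

  idx_pos <- which(y == 1)
  idx_neg <- which(y == -1)
  m_pos <- max(1L, round(subsample * length(idx_pos)))
  m_neg <- max(1L, round(subsample * length(idx_neg)))
  m_sub <- m_pos + m_neg

  remaining <- seq_len(K)
  order_out <- integer(0)
  rounds <- list()
  r <- 0L
  while (length(remaining) > 0L) {
    r <- r + 1L
    importance <- numeric(length(remaining))
    dual_attr <- numeric(length(remaining))
    n_ok <- 0L
    if (length(remaining) >= m_sub && r <= max_lp_rounds && m_sub >= 2L) {
      Ar <- X[, remaining, drop = FALSE]
      for (s in seq_len(n_solves)) {
        rows <- c(sample(idx_pos, m_pos), sample(idx_neg, m_neg))
        sol <- solve_min_l1(Ar[rows, , drop = FALSE], y[rows],
                            feas_tol = feas_tol, support_tol = support_tol)
        if (sol$status == "optimal") {
          importance <- importance + abs(sol$w)
          dual_attr <- dual_attr + sol$dual
          n_ok <- n_ok + 1L
        }
      }
      if (n_ok > 0L) {
        importance <- importance / n_ok
        dual_attr <- dual_attr / n_ok
      }
    }
    if (n_ok == 0L) {
      # terminal fallback: the LP can no longer run; order every remaining
      # voxel by decreasing |t|
      ord <- order(-tabs[remaining], remaining)
      order_out <- c(order_out, remaining[ord])
      rounds[[r]] <- data.frame(round = r, lp_solves = n_ok,
                                selected = length(remaining),
                                fallback = TRUE)
      remaining <- integer(0)
      break
    }
    take <- min(batch_size, length(remaining))
    sel <- order(-dual_attr, -importance, -tabs[remaining],
                 remaining)[seq_len(take)]
    order_out <- c(order_out, remaining[sel])
    rounds[[r]] <- data.frame(round = r, lp_solves = n_ok, selected = take,
                              fallback = FALSE)
    remaining <- remaining[-sel]
  }
  bw <- assign_batch_weights(order_out, batch_size)
  attr(bw, "rounds") <- do.call(rbind, rounds)
  bw
}

#' Export a batch weighting as a table
#'
#' @param weighting a [assign_batch_weights()] result.
#' @param mask optional [brain_mask()] for coordinates.
#' @return Data frame with `voxel_col`, `selection_rank`, `batch`, `weight`
#'   (plus `x`, `y`, `z` when a mask is given).
#' @export
weighting_table <- function(weighting, mask = NULL) {
  out <- data.frame(voxel_col = weighting$order,
                    selection_rank = seq_along(weighting$order),
                    batch = weighting$batch, weight = weighting$weights)
  if (!is.null(mask)) {
    co <- mask_coords(mask, weighting$order)
    out <- cbind(out, as.data.frame(co))
  }
  out
}
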