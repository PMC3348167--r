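test_that("fold plans are stratified, seeded and cover LOOCV", {
  y <- rep(c(1L, -1L), each = 10L)
  plan <- make_folds(y, 10L, seed = 1L)
  for (f in 1:10) {
    expect_equal(sum(plan$assignments == f & y == 1L), 1L)
    expect_equal(sum(plan$assignments == f & y == -1L), 1L)
  }
  expect_identical(plan, make_folds(y, 10L, seed = 1L))
  expect_false(identical(plan$assignments,
                         make_folds(y, 10L, seed = 2L)$assignments))

  loo <- make_folds(y, 20L, seed = 1L)
  expect_equal(sort(loo$assignments), 1:20)

  y_small <- rep(c(1L, -1L), c(3L, 17L))
  expect_error(make_folds(y_small, 10L), "fewer subjects than folds")
  plan2 <- make_folds(y_small, 10L, seed = 1L, allow_unstratified = TRUE)
  expect_equal(sort(unique(plan2$assignments)), 1:10)
})

test_that("held-out subjects never influence selection or standardization", {
  gen <- make_separable_cohort()
  co <- gen$cohort
  plan <- make_folds(co$labels, 5L, seed = 2L)
  pars <- pipeline_params(filter_k = 200L, batch_size = 20L,
                          n_classify = 20L, n_solves = 6L)
  fr <- run_fold(co, plan, 1L, pars)

  co_corrupt <- co
  co_corrupt$X[fr$test_idx, ] <- matrix(rnorm(length(fr$test_idx) * ncol(co$X)),
                                        length(fr$test_idx))
  fr2 <- run_fold(co_corrupt, plan, 1L, pars)
  expect_identical(fr$weighting$order, fr2$weighting$order)
  expect_identical(fr$weighting$weights, fr2$weighting$weights)

  expect_false(any(fr$test_idx %in% which(plan$assignments != 1L)))
})

test_that("perfectly separable cohorts classify perfectly in every fold", {
  gen <- make_separable_cohort()
  co <- gen$cohort
  pars <- pipeline_params(filter_k = 200L, batch_size = 20L,
                          n_classify = 20L, pattern_size = 50L,
                          n_solves = 6L)
  cv <- run_cv(co, pars, M = 5L, seed = 2L)
  for (fr in cv$folds) expect_equal(fr$metrics$GR, 1)
  expect_equal(cv$pooled$GR, 1)

  # fold confusion counts aggregate exactly to the pooled confusion
  agg <- Reduce(`+`, lapply(cv$folds, function(f)
    c(f$metrics$TP, f$metrics$FN, f$metrics$TN, f$metrics$FP)))
  expect_equal(agg, c(cv$pooled$TP, cv$pooled$FN, cv$pooled$TN, cv$pooled$FP))
})

test_that("consensus pattern matches a hand-worked mean-weight example", {
  fw <- function(order, weights) list(order = order, weights = weights)
  folds <- list(
    fw(c(1L, 2L, 3L, 4L, 5L), c(1, .8, .6, .4, .2)),
    fw(c(2L, 1L, 5L, 7L, 9L), c(1, .8, .6, .4, .2)),
    fw(c(5L, 2L, 1L, 8L, 10L), c(1, .8, .6, .4, .2))
  )
  expect_warning(cp <- consensus_pattern(folds, top_n = 5L), "3 voxels")
  expect_equal(cp$voxels, c(2L, 1L, 5L))
  expect_equal(cp$mean_weight, c(mean(c(.8, 1, .8)), mean(c(1, .8, .6)),
                                 mean(c(.2, .6, 1))), tolerance = 1e-12)
  expect_equal(cp$fold_presence, c(3L, 3L, 3L))

  cp2 <- consensus_pattern(folds, top_n = 2L)
  expect_equal(cp2$voxels, c(2L, 1L))

  same <- list(fw(1:5, seq(1, .2, by = -.2)), fw(1:5, seq(1, .2, by = -.2)))
  cp3 <- consensus_pattern(same, top_n = 3L)
  expect_equal(cp3$voxels, 1:3)

  disjoint <- list(fw(1:3, c(1, .5, .25)), fw(4:6, c(1, .5, .25)))
  expect_warning(cp4 <- consensus_pattern(disjoint, top_n = 2L),
                 "empty intersection")
  expect_length(cp4$voxels, 0L)
})

test_that("a pattern transfers to a second cohort and validates its grid", {
  gen <- make_separable_cohort(seed = 7L)
  co <- gen$cohort
  pars <- pipeline_params(filter_k = 200L, batch_size = 20L,
                          n_classify = 20L, pattern_size = 20L,
                          n_solves = 6L)
  cv <- run_cv(co, pars, M = 5L, seed = 2L)

  self <- apply_pattern(cv$consensus, co)
  expect_equal(self$metrics$GR, 1)

  gen2 <- make_separable_cohort(seed = 8L)
  transfer <- apply_pattern(cv$consensus, gen2$cohort)
  expect_gte(transfer$metrics$GR, 0.9)

  other_grid <- vbm_cohort(matrix(runif(40 * 8), 40, 8), gen$cohort$ages,
                           gen$cohort$labels,
                           brain_mask(array(TRUE, c(2, 2, 2))))
  expect_error(apply_pattern(cv$consensus, other_grid), "grid")

  pat_bad <- cv$consensus
  pat_bad$grid_shape <- NULL
  pat_bad$voxels <- c(pat_bad$voxels, ncol(co$X) + 5L)
  expect_error(apply_pattern(pat_bad, other_grid), "outside")
})

test_that("consensus patterns are stable across cross-validation seeds", {
  gen <- make_midsize_cohort(seed = 5L)
  co <- gen$cohort
  pars <- pipeline_params(filter_k = ncol(co$X), batch_size = 30L,
                          n_classify = 30L, pattern_size = 60L,
                          n_solves = 8L)
  cv_a <- run_cv(co, pars, M = 5L, seed = 11L)
  cv_b <- run_cv(co, pars, M = 5L, seed = 99L)
  jac <- length(intersect(cv_a$consensus$voxels, cv_b$consensus$voxels)) /
    length(union(cv_a$consensus$voxels, cv_b$consensus$voxels))
  expect_gte(jac, 0.5)
})
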