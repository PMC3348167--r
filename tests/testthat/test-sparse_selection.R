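test_that("exact minimum-1-norm solutions on worked instances", {
  s <- solve_min_l1(rbind(c(1, 0), c(0, 1)), c(1, -1))
  expect_equal(s$w, c(1, -1), tolerance = 1e-10)
  expect_equal(s$l1_norm, 2, tolerance = 1e-10)
  expect_equal(s$status, "optimal")

  # between two proportional columns the larger-magnitude one wins the
  # 1-norm (duplicated row keeps the system consistent)
  s2 <- solve_min_l1(rbind(c(1, 2), c(1, 2)), c(1, 1))
  expect_equal(s2$w, c(0, 0.5), tolerance = 1e-10)
  expect_equal(s2$l1_norm, 0.5, tolerance = 1e-10)

  s3 <- solve_min_l1(rbind(c(1, 1), c(2, 2)), c(1, 1))
  expect_equal(s3$status, "infeasible")

  expect_error(solve_min_l1(matrix(1, 2, 1), c(1, 2)), "\\+1 or -1")
})

test_that("simplex equals the vertex-enumeration oracle on random instances", {
  set.seed(30)
  for (i in 1:25) {
    A <- matrix(runif(24, -1, 1), 3, 8)
    y <- sample(c(-1, 1), 3, replace = TRUE)
    s <- solve_min_l1(A, y)
    expect_equal(s$l1_norm, enum_min_l1(A, y), tolerance = 1e-8)
    expect_lt(s$residual_inf, 1e-7)
    expect_lte(length(s$support), 4L)
  }
  for (i in 1:10) {
    A <- matrix(runif(40, -1, 1), 4, 10)
    y <- sample(c(-1, 1), 4, replace = TRUE)
    s <- solve_min_l1(A, y)
    expect_equal(s$l1_norm, enum_min_l1(A, y), tolerance = 1e-8)
    expect_lte(length(s$support), 5L)
  }
})

test_that("dual attractiveness is 1 on the support and <= 1 elsewhere", {
  set.seed(31)
  A <- matrix(runif(30, -1, 1), 3, 10)
  s <- solve_min_l1(A, c(1, -1, 1))
  expect_equal(s$dual[s$support], rep(1, length(s$support)),
               tolerance = 1e-8)
  expect_true(all(s$dual <= 1 + 1e-8))
})

test_that("batch weights follow the descending ladder", {
  bw <- assign_batch_weights(seq_len(20000L), 200L)
  expect_equal(bw$n_batches, 100L)
  expect_equal(unique(bw$weights), seq(1, 0.01, by = -0.01),
               tolerance = 1e-12)
  expect_equal(bw$weights[1:200], rep(1, 200))

  bw2 <- assign_batch_weights(seq_len(400L), 200L)
  expect_equal(bw2$weights, rep(c(1, 0.5), each = 200))

  bw3 <- assign_batch_weights(seq_len(5L), 2L)
  expect_equal(bw3$weights, c(1, 1, 2 / 3, 2 / 3, 1 / 3))
  expect_equal(bw3$batch, c(1L, 1L, 2L, 2L, 3L))

  expect_error(assign_batch_weights(integer(0), 2L), "non-empty")
})

test_that("recursive selection finds planted columns first and is seeded", {
  co <- make_planted_cohort(n_per_group = 10L, n_signal = 3L, n_noise = 50L)
  std <- standardize_fit(co$X)
  Xs <- standardize_apply(co$X, std)
  bw <- recursive_select(Xs, co$labels, batch_size = 10L, seed = 2L)
  expect_true(all(c(1L, 2L, 3L) %in% bw$order[1:10]))
  expect_setequal(bw$order, seq_len(ncol(co$X)))

  bw_again <- recursive_select(Xs, co$labels, batch_size = 10L, seed = 2L)
  expect_identical(bw$order, bw_again$order)

  bw_all <- recursive_select(Xs, co$labels, batch_size = ncol(Xs), seed = 2L)
  expect_equal(bw_all$n_batches, 1L)
  expect_true(all(bw_all$weights == 1))

  rounds <- attr(bw, "rounds")
  expect_true(all(rounds$lp_solves[!rounds$fallback] > 0L))
})

test_that("support size respects the basic-solution bound across rounds", {
  co <- make_planted_cohort(n_per_group = 8L, n_signal = 2L, n_noise = 40L,
                            seed = 9L)
  Xs <- standardize_apply(co$X, standardize_fit(co$X))
  set.seed(33)
  for (i in 1:10) {
    rows <- c(sample(which(co$labels == 1), 6), sample(which(co$labels == -1), 6))
    s <- solve_min_l1(Xs[rows, ], co$labels[rows])
    if (s$status == "optimal") expect_lte(length(s$support), 13L)
  }
})
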