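test_that("smoothing preserves mass, constants and the delta-peak value", {
  set.seed(10)
  v <- array(runif(8 * 8 * 8), c(8, 8, 8))
  expect_identical(smooth_field(v, 0), v)
  expect_equal(smooth_field(array(0.7, c(6, 6, 6)), 3),
               array(0.7, c(6, 6, 6)), tolerance = 1e-12)
  sm <- smooth_field(v, 2.5)
  expect_equal(sum(sm), sum(v), tolerance = 1e-6)
  expect_error(smooth_field(v, -1), ">= 0")

  # delta impulse, FWHM chosen so sigma = 1: peak of the 3-D Gaussian
  # kernel is (2*pi)^(-3/2)
  d <- array(0, c(21, 21, 21))
  d[11, 11, 11] <- 1
  peak <- smooth_field(d, 2 * sqrt(2 * log(2)))[11, 11, 11]
  expect_equal(peak, (2 * pi)^(-3 / 2), tolerance = 2e-3)
})

test_that("generated cohorts have the requested structure and are seeded", {
  gen <- make_separable_cohort(seed = 3L)
  expect_equal(nrow(gen$cohort$X), 40L)
  expect_equal(sum(gen$cohort$labels), 0L)
  expect_true(all(gen$cohort$ages[gen$cohort$labels == 1L] <= 30))
  expect_true(all(gen$cohort$ages[gen$cohort$labels == -1L] >= 50))

  gen2 <- make_separable_cohort(seed = 3L)
  expect_identical(gen, gen2)
  gen3 <- make_separable_cohort(seed = 4L)
  expect_false(identical(gen$cohort$X, gen3$cohort$X))
})

test_that("planted slope is exact in the noiseless limit", {
  spec <- synthetic_spec(grid_shape = c(6L, 6L, 5L), n_young = 10L,
                         n_old = 10L, noise_sd = 1e-13,
                         smooth_fwhm_voxels = 0,
                         clusters = list(cluster_spec("c", c(3L, 3L, 3L),
                                                      "direct", -0.01,
                                                      n_voxels = 8L)),
                         seed = 1L)
  gen <- generate_cohort(spec)
  for (j in gen$truth$cluster_cols$c[1:3]) {
    b <- coef(lm(gen$cohort$X[, j] ~ gen$cohort$ages))[2L]
    expect_equal(unname(b), -0.01, tolerance = 1e-10)
  }
})

test_that("per-voxel OLS slopes recover the planted value within 3 SE", {
  spec <- synthetic_spec(grid_shape = c(12L, 12L, 7L), n_young = 100L,
                         n_old = 100L, noise_sd = 0.05,
                         smooth_fwhm_voxels = 2,
                         clusters = list(cluster_spec("c", c(6L, 6L, 4L),
                                                      "direct", -0.01,
                                                      n_voxels = 40L)),
                         seed = 11L)
  gen <- generate_cohort(spec)
  ok <- vapply(gen$truth$cluster_cols$c, function(j) {
    sm <- summary(lm(gen$cohort$X[, j] ~ gen$cohort$ages))$coefficients
    abs(sm[2, "Estimate"] - (-0.01)) <= 3 * sm[2, "Std. Error"]
  }, TRUE)
  expect_gte(mean(ok), 0.99)
})

test_that("invalid cluster layouts are rejected", {
  expect_error(synthetic_spec(clusters = list(
    cluster_spec("a", c(5L, 5L, 5L), "direct", -0.01, n_voxels = 40L),
    cluster_spec("b", c(6L, 5L, 5L), "direct", -0.01, n_voxels = 40L)
  )), "overlap")
  expect_error(cluster_cols(cluster_spec("e", c(1L, 1L, 1L), "direct",
                                         -0.01, radius = 3),
                            c(20L, 20L, 10L)), "outside the grid")
  expect_error(cluster_spec("c", c(5L, 5L, 5L), "covarying", -0.001,
                            n_voxels = 10L), "partner")
  expect_error(synthetic_spec(clusters = list(
    cluster_spec("c", c(5L, 5L, 5L), "covarying", -0.001, n_voxels = 10L,
                 partner = "nope")
  )), "existing direct partner")
  expect_error(synthetic_spec(young_age_range = c(18, 60),
                              old_age_range = c(50, 91)), "overlap")
})

test_that("covarying voxels are marginally weaker than direct voxels", {
  gen <- make_study_cohort(seed = 202L, covarying = TRUE)
  tsc <- abs(voxelwise_tscore(gen$cohort))
  rank_of <- rank(-tsc, ties.method = "first")
  direct <- unlist(gen$truth$cluster_cols[c("direct1", "direct2", "direct3")])
  covar <- gen$truth$cluster_cols$covary1
  expect_gt(mean(rank_of[covar]), mean(rank_of[direct]))
})
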