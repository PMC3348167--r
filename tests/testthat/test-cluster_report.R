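test_that("connectivity semantics split or join voxel pairs as expected", {
  m <- brain_mask(array(TRUE, c(5, 5, 5)))
  face_pair <- coords_to_cols(m, rbind(c(2, 2, 2), c(3, 2, 2)))
  cl6 <- connected_clusters(face_pair, m, 6L)
  expect_length(cl6, 1L)
  expect_equal(cl6[[1]]$size, 2L)

  diag_pair <- coords_to_cols(m, rbind(c(2, 2, 2), c(3, 3, 2)))
  expect_length(connected_clusters(diag_pair, m, 6L), 2L)
  expect_length(connected_clusters(diag_pair, m, 18L), 1L)

  corner_pair <- coords_to_cols(m, rbind(c(2, 2, 2), c(3, 3, 3)))
  expect_length(connected_clusters(corner_pair, m, 18L), 2L)
  expect_length(connected_clusters(corner_pair, m, 26L), 1L)

  single <- connected_clusters(coords_to_cols(m, rbind(c(1, 1, 1))), m)
  expect_equal(single[[1]]$size, 1L)
})

test_that("components match an independent union-find oracle", {
  uf_components <- function(coords, conn) {
    n <- nrow(coords)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    lim <- switch(as.character(conn), "6" = 1L, "18" = 2L, "26" = 3L)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) {
        d <- abs(coords[i, ] - coords[j, ])
        if (max(d) <= 1 && sum(d) <= lim && sum(d) > 0) {
          parent[find(i)] <- find(j)
        }
      }
    }
    length(unique(vapply(seq_len(n), find, 0L)))
  }
  set.seed(50)
  m <- brain_mask(array(TRUE, c(6, 6, 6)))
  for (rep in 1:5) {
    vox <- sample(m$n_voxels, 20L)
    co <- mask_coords(m, vox)
    for (conn in c(6L, 18L, 26L)) {
      cl <- connected_clusters(vox, m, conn)
      expect_equal(length(cl), uf_components(co, conn))
      expect_setequal(unlist(lapply(cl, `[[`, "voxels")), vox)
      expect_equal(sum(vapply(cl, `[[`, 0L, "size")), 20L)
    }
  }
})

test_that("cluster age regression recovers planted slopes and handles degeneracy", {
  m <- brain_mask(array(TRUE, c(4, 4, 2)))
  ages <- seq(20, 88, length.out = 12)
  X <- matrix(2, 12, 32)
  X[, 1:4] <- 2 - 0.01 * ages
  co <- vbm_cohort(X, ages, rep(c(1L, -1L), each = 6L), m)

  r <- cluster_age_regression(co, 1:4)
  expect_equal(r$slope_b, -0.01, tolerance = 1e-12)
  expect_equal(r$slope_p, 0)
  expect_true(r$declines)

  r0 <- cluster_age_regression(co, 5:8)
  expect_equal(r0$slope_b, 0, tolerance = 1e-12)
  expect_equal(r0$slope_p, 1)
  expect_false(r0$declines)

  co_flat <- vbm_cohort(X, rep(50, 12), co$labels, m)
  expect_error(cluster_age_regression(co_flat, 1:4), "zero age variance")

  # normal-equations oracle on noisy data
  set.seed(51)
  Xn <- X + matrix(rnorm(12 * 32, 0, 0.05), 12, 32)
  con <- vbm_cohort(Xn, ages, co$labels, m)
  rn <- cluster_age_regression(con, 1:4)
  mv <- rowMeans(Xn[, 1:4])
  n <- length(ages)
  sxx <- sum((ages - mean(ages))^2)
  b <- sum((ages - mean(ages)) * (mv - mean(mv))) / sxx
  a <- mean(mv) - b * mean(ages)
  s2 <- sum((mv - a - b * ages)^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  p <- 2 * pt(abs(b / se), df = n - 2, lower.tail = FALSE)
  expect_equal(rn$slope_b, b, tolerance = 1e-10)
  expect_equal(rn$slope_se, se, tolerance = 1e-10)
  expect_equal(rn$slope_p, p, tolerance = 1e-10)
})

test_that("decline fraction is 1 for planted decline and ~0.5 under permutation", {
  gen <- make_midsize_cohort(seed = 6L)
  co <- gen$cohort
  planted <- unlist(gen$truth$cluster_cols)
  vc <- volume_change_fraction(planted, co)
  expect_equal(vc$fraction, 1)

  set.seed(52)
  co_perm <- co
  co_perm$labels <- sample(co$labels)
  vc_perm <- volume_change_fraction(sample(ncol(co$X), 100L), co_perm)
  expect_lt(abs(vc_perm$fraction - 0.5), 0.2)

  expect_warning(vc0 <- volume_change_fraction(integer(0), co), "empty")
  expect_equal(vc0$n_voxels, 0L)
  expect_true(is.na(vc0$fraction))
})

test_that("voxel pairs outperform singles only through covariation", {
  gen <- make_study_cohort(seed = 303L, covarying = TRUE)
  co <- gen$cohort
  tsc <- abs(voxelwise_tscore(co))
  d1 <- gen$truth$cluster_cols$direct1
  cv1 <- gen$truth$cluster_cols$covary1
  rep_d <- d1[which.max(tsc[d1])]
  rep_c <- cv1[which.max(tsc[cv1])]
  plan <- make_folds(co$labels, 10L, seed = 4L)

  pw <- pairwise_voxel_discrimination(co, rep_d, rep_c, plan)
  expect_gt(pw$acc_pair, max(pw$acc_a, pw$acc_b))
  expect_gt(pw$acc_a, pw$acc_b)  # the direct voxel is the stronger single

  noise <- which(gen$truth$true_slope == 0 & gen$truth$loading == 0)
  pw0 <- pairwise_voxel_discrimination(co, noise[1], noise[2], plan)
  expect_lt(abs(pw0$acc_a - 0.5), 0.15)
  expect_lt(abs(pw0$acc_pair - 0.5), 0.15)

  expect_error(pairwise_voxel_discrimination(co, rep_d, rep_d, plan),
               "distinct")
})
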