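test_that("voxel-wise GLM with no covariates equals the pooled two-sample t", {
  set.seed(10)
  n1 <- 7; n2 <- 9
  dims <- c(4, 4, 3)
  mask <- full_mask(dims)
  nv <- prod(dims)
  Y <- matrix(rnorm(nv * (n1 + n2)), nv)
  group <- rep(c(1, 0), c(n1, n2))
  sm <- fit_voxelwise_glm(Y, group, covariates = NULL, mask = mask)
  tor <- vapply(seq_len(nv), function(v)
    oracle_two_sample_t(Y[v, group == 1], Y[v, group == 0]), 0)
  expect_lt(max(abs(as.vector(sm$t) - tor)), 1e-10)
  expect_equal(sm$df, n1 + n2 - 2)
  expect_true(all(sm$p[mask$mask] > 0 & sm$p[mask$mask] <= 1))
})

test_that("identical groups give t = 0 and p = 1", {
  dims <- c(3, 3, 3)
  mask <- full_mask(dims)
  block <- matrix(rnorm(prod(dims) * 5), prod(dims))
  Y <- cbind(block, block)          # both groups identical data
  group <- rep(c(1, 0), each = 5)
  sm <- fit_voxelwise_glm(Y, group, covariates = NULL, mask = mask)
  expect_equal(as.vector(sm$t), rep(0, prod(dims)))
  expect_equal(as.vector(sm$p), rep(1, prod(dims)))
})

test_that("an orthogonal covariate leaves the group coefficient and RSS alone and rescales t by the df change", {
  set.seed(11)
  n <- 16
  dims <- c(2, 2, 2)
  mask <- full_mask(dims)
  nv <- prod(dims)
  Y <- matrix(rnorm(nv * n), nv)
  group <- rep(c(1, 0), each = n / 2)
  # covariate orthogonal to the intercept, the group column and every voxel
  D0 <- cbind(1, group)
  cand <- rnorm(n)
  basis <- cbind(D0, t(Y))
  cov_orth <- cand - basis %*% solve(crossprod(basis), crossprod(basis, cand))
  sm0 <- fit_voxelwise_glm(Y, group, covariates = NULL, mask = mask)
  sm1 <- fit_voxelwise_glm(Y, group, covariates = cbind(cov_orth),
                           mask = mask)
  expect_equal(sm1$df, sm0$df - 1)
  # projection oracle: the coefficient and RSS are unchanged, so
  # sigma^2 = RSS/df grows and t shrinks by exactly sqrt(df_new / df_old)
  expect_equal(as.vector(sm1$t), as.vector(sm0$t) * sqrt(sm1$df / sm0$df),
               tolerance = 1e-8)
})

test_that("a collinear design is rejected with the offending columns named", {
  dims <- c(2, 2, 2)
  mask <- full_mask(dims)
  Y <- matrix(rnorm(8 * 10), 8)
  group <- rep(c(1, 0), each = 5)
  expect_error(
    fit_voxelwise_glm(Y, group, covariates = cbind(dup = group), mask = mask),
    "collinear")
})

test_that("residual smoothness estimation recovers applied smoothing and is monotone", {
  dims <- c(32, 32, 32)
  mask <- brain_mask(array(TRUE, dims), c(3, 3, 3))
  gen_maps <- function(fwhm, n, seed) {
    set.seed(seed)
    lapply(seq_len(n), function(i) {
      a <- array(rnorm(prod(dims)), dims)
      if (fwhm > 0) a <- smooth_gaussian(a, fwhm, voxel_size_mm = c(3, 3, 3))
      a
    })
  }
  # white noise: no measurable smoothness -> about one voxel width
  # (rho hovers around zero, so the no-smoothness warning may or may not fire)
  f0 <- suppressWarnings(estimate_smoothness(gen_maps(0, 4, 1), mask))
  expect_true(all(as.numeric(f0) <= 4.5))   # clamped near 3 mm voxels
  # known 8 mm smoothing recovered within 15% from 30 maps
  f8 <- estimate_smoothness(gen_maps(8, 30, 2), mask)
  expect_true(all(abs(as.numeric(f8) - 8) / 8 < 0.15))
  # monotone: stronger applied smoothing gives a larger estimate
  f12 <- estimate_smoothness(gen_maps(12, 10, 3), mask)
  f6 <- estimate_smoothness(gen_maps(6, 10, 3), mask)
  expect_true(all(as.numeric(f12) > as.numeric(f6)))
})

test_that("Monte Carlo cluster threshold handles degenerate and invalid settings", {
  mask <- full_mask(c(8, 8, 8))
  # alpha = 1: any cluster passes
  expect_equal(as.integer(monte_carlo_cluster_threshold(
    mask, 0, voxel_p = 0.01, alpha = 1, n_iter = 100, seed = 1)), 1L)
  # alpha below MC resolution is an error advising more iterations
  expect_error(monte_carlo_cluster_threshold(
    mask, 0, voxel_p = 0.01, alpha = 0.001, n_iter = 100), "n_iter")
  # deterministic given a seed
  k1 <- monte_carlo_cluster_threshold(mask, 4, 0.01, 0.05, 200, seed = 4)
  k2 <- monte_carlo_cluster_threshold(mask, 4, 0.01, 0.05, 200, seed = 4)
  expect_identical(as.integer(k1), as.integer(k2))
})

test_that("cluster extraction applies threshold, size gate and canonical ordering", {
  dims <- c(12, 12, 12)
  mask <- full_mask(dims)
  mk_stat <- function(tarr, df = 50) {
    parr <- 2 * pt(-abs(tarr), df)
    structure(list(t = tarr, p = parr, df = df), class = "stat_map")
  }
  # all-zero map: no clusters
  cl0 <- extract_clusters(mk_stat(array(0, dims)), mask, 0.001, 1)
  expect_equal(nrow(cl0$clusters), 0)
  # planted 5x5x5 block of t = 10 (125 voxels)
  tarr <- array(0, dims); tarr[4:8, 4:8, 4:8] <- 10
  kept <- extract_clusters(mk_stat(tarr), mask, 0.001, 60)
  expect_equal(nrow(kept$clusters), 1)
  expect_equal(kept$clusters$size_voxels, 125)
  gone <- extract_clusters(mk_stat(tarr), mask, 0.001, 126)
  expect_equal(nrow(gone$clusters), 0)
  edge <- extract_clusters(mk_stat(tarr), mask, 0.001, 125)
  expect_equal(nrow(edge$clusters), 1)   # the gate is >=, not >
  # two clusters of different size and sign: ordered by descending size,
  # sign recorded, peak inside each block
  tarr2 <- array(0, dims)
  tarr2[2:4, 2:4, 2:4] <- 8            # 27 voxels, positive
  tarr2[7:10, 7:10, 7:10] <- -9        # 64 voxels, negative
  cl2 <- extract_clusters(mk_stat(tarr2), mask, 0.001, 1)
  expect_equal(cl2$clusters$size_voxels, c(64, 27))
  expect_equal(cl2$clusters$sign, c(-1, 1))
  expect_equal(cl2$clusters$label, c(1, 2))
  expect_true(all(cl2$cluster_mask[7:10, 7:10, 7:10] == 1))
  # labels of one cluster are face-connected: diagonal blocks split at
  # 6-connectivity but merge at 26
  tarr3 <- array(0, dims)
  tarr3[2:3, 2:3, 2:3] <- 7
  tarr3[4:5, 4:5, 4:5] <- 7            # touches only at a corner
  cl6 <- extract_clusters(mk_stat(tarr3), mask, 0.001, 1, connectivity = 6)
  cl26 <- extract_clusters(mk_stat(tarr3), mask, 0.001, 1, connectivity = 26)
  expect_equal(nrow(cl6$clusters), 2)
  expect_equal(nrow(cl26$clusters), 1)
})
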