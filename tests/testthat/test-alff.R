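test_that("dummy-scan removal drops exactly the leading frames", {
  b <- random_bold(c(6, 6, 6), nt = 240)
  b2 <- drop_dummies(b, 10)
  expect_equal(n_timepoints(b2), 230)
  expect_equal(b2$data[, , , 1], b$data[, , , 11])
  expect_identical(drop_dummies(b, 0), b)
  expect_error(drop_dummies(b, 240), "dummy")
})

test_that("motion QC applies strict limits", {
  expect_true(motion_qc(1.0, 1.0))
  expect_false(motion_qc(2.0, 0))      # translation at the limit fails
  expect_false(motion_qc(0, 2.0))      # rotation at the limit fails
  expect_true(motion_qc(0, 0))
  expect_true(motion_qc(1.999, 1.999))
  expect_error(motion_qc(-1, 0), "nonnegative")
})

test_that("linear detrending removes lines and leaves residuals orthogonal to them", {
  dims <- c(4, 4, 4)
  nt <- 30
  # pure lines (random intercepts and slopes) vanish
  set.seed(2)
  a <- rnorm(prod(dims)); s <- rnorm(prod(dims))
  lines <- outer(a, rep(1, nt)) + outer(s, seq_len(nt))
  b <- bold4d(array(lines, c(dims, nt)), c(3, 3, 3), 2)
  expect_lt(max(abs(detrend_linear(b)$data)), 1e-8)
  # constant series vanish too
  b0 <- bold4d(array(5, c(dims, nt)), c(3, 3, 3), 2)
  expect_lt(max(abs(detrend_linear(b0)$data)), 1e-10)
  # random series: residuals orthogonal to [1, t] (normal-equation oracle)
  br <- random_bold(dims, nt, seed = 3)
  res <- matrix(detrend_linear(br)$data, ncol = nt)
  expect_lt(max(abs(res %*% rep(1, nt))), 1e-8)
  expect_lt(max(abs(res %*% seq_len(nt))), 1e-6)
})

test_that("Gaussian smoothing is identity at fwhm 0, conserves constants, and matches the separable closed form on an impulse", {
  b <- random_bold(c(8, 8, 8), nt = 4)
  expect_identical(smooth_gaussian(b, 0), b)
  cons <- array(3.5, c(9, 9, 9))
  sm <- smooth_gaussian(cons, 8, voxel_size_mm = c(3, 3, 3))
  expect_equal(sm, cons, tolerance = 1e-12)
  # unit impulse at the center of a 17^3 grid, 8 mm fwhm on 4 mm voxels:
  # response = outer product of the normalized sampled 1D kernels
  imp <- array(0, c(17, 17, 17)); imp[9, 9, 9] <- 1
  out <- smooth_gaussian(imp, 8, voxel_size_mm = c(4, 4, 4))
  sigma <- 8 / (2 * sqrt(2 * log(2))) / 4
  r <- ceiling(4 * sigma)
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  kfull <- rep(0, 17); kfull[9 + (-r:r)] <- k1
  expected <- outer(outer(kfull, kfull), kfull)
  expect_lt(max(abs(out - expected)), 1e-6)
  expect_equal(sum(out), 1, tolerance = 1e-10)   # mass conserved
})

test_that("nuisance regression projects out confounds", {
  b <- random_bold(c(4, 4, 4), nt = 40, seed = 5)
  # no confounds: mean-centering only
  r0 <- regress_nuisance(b)
  expect_lt(max(abs(apply(r0$data, 1:3, mean))), 1e-10)
  # confound equal to the voxel series itself: residual is zero there
  conf <- b$data[1, 1, 1, ]
  r1 <- regress_nuisance(b, cbind(conf))
  expect_lt(max(abs(r1$data[1, 1, 1, ])), 1e-8)
  # residuals orthogonal to all confound columns (projection oracle)
  conf2 <- cbind(rnorm(40), sin(seq_len(40)))
  r2 <- regress_nuisance(b, conf2)
  res <- matrix(r2$data, ncol = 40)
  expect_lt(max(abs(res %*% conf2)), 1e-8)
  # rank-deficient confounds fall back to the pseudo-inverse with a warning
  expect_warning(r3 <- regress_nuisance(b, cbind(conf, conf)), "rank")
  expect_lt(max(abs(r3$data[1, 1, 1, ])), 1e-8)
})

test_that("ALFF follows its spectral definition", {
  dims <- c(3, 3, 3)
  mask <- full_mask(dims)
  nt <- 230; tr <- 2
  tt <- (0:(nt - 1))
  # closed-band bin inclusion at N = 230, TR = 2: k/460 in [0.01, 0.08]
  b <- random_bold(dims, nt, seed = 6)
  a <- compute_alff(b, mask, c(0.01, 0.08))
  expect_equal(a$n_bins, sum(seq_len(115) / 460 >= 0.01 - 1e-9 &
                               seq_len(115) / 460 <= 0.08 + 1e-9))
  # exact-bin cosine: amplitude A vs 2A gives ALFF ratio 2 (homogeneity)
  k <- 10                               # f = 10/460 Hz, inside the band
  cosr <- cos(2 * pi * k * tt / nt)
  mk <- function(amp) bold4d(array(rep(amp * cosr, each = prod(dims)),
                                   c(dims, nt)), c(3, 3, 3), tr)
  a1 <- compute_alff(mk(1), mask)$data[1, 1, 1]
  a2 <- compute_alff(mk(2), mask)$data[1, 1, 1]
  expect_equal(a2 / a1, 2, tolerance = 1e-10)
  # a unit cosine at a bin frequency scores amplitude 1 at that bin
  nb <- compute_alff(mk(1), mask)$n_bins
  expect_equal(a1 * nb, 1, tolerance = 1e-10)
  # out-of-band energy does not leak in: 0.2 Hz cosine vs in-band cosine
  out_cos <- cos(2 * pi * 0.2 * tt * tr)   # 0.2 Hz > 0.08 Hz; exact bin
  aout <- compute_alff(bold4d(array(rep(out_cos, each = prod(dims)),
                                    c(dims, nt)), c(3, 3, 3), tr),
                       mask)$data[1, 1, 1]
  expect_lt(aout, 1e-10 * a1)
  # empty band is a configuration error naming the offending combination
  expect_error(compute_alff(random_bold(dims, 10), mask,
                            c(0.0001, 0.0002)), "band")
  # band above Nyquist rejected
  expect_error(compute_alff(b, mask, c(0.01, 0.3)), "Nyquist")
})

test_that("ALFF equals the brute-force periodogram oracle and scales linearly", {
  dims <- c(5, 5, 4)
  nt <- 64
  mask <- full_mask(dims)
  b <- random_bold(dims, nt, seed = 7)
  a <- compute_alff(b, mask, c(0.01, 0.08))
  M <- matrix(b$data, ncol = nt)
  oracle <- apply(M, 1, oracle_alff_series, tr = 2, band = c(0.01, 0.08))
  expect_lt(max(abs(as.vector(a$data) - oracle) / oracle), 1e-10)
  # scale equivariance: multiplying the series by c multiplies ALFF by c
  b3 <- b; b3$data <- b$data * 3.7
  a3 <- compute_alff(b3, mask, c(0.01, 0.08))
  expect_equal(a3$data, a$data * 3.7, tolerance = 1e-12)
})

test_that("per-bin amplitudes satisfy the Parseval identity", {
  # odd N, mean-centered series: sum over all positive-frequency bins of
  # a_k^2 equals 2 * sum(x^2) / N for amplitude a_k = 2|X_k|/N
  nt <- 31; tr <- 2
  set.seed(8)
  x <- rnorm(nt); x <- x - mean(x)
  dims <- c(1, 1, 1)
  b <- bold4d(array(x, c(dims, nt)), c(3, 3, 3), tr)
  mask <- full_mask(dims)
  amps <- vapply(seq_len((nt - 1) / 2), function(k) {
    f <- k / (nt * tr)
    compute_alff(b, mask, c(f - 1e-6, f + 1e-6))$data[1, 1, 1]
  }, 0)
  expect_equal(sum(amps^2), 2 * sum(x^2) / nt, tolerance = 1e-8)
})

test_that("mALFF normalization forces unit mask mean and is scale-free", {
  dims <- c(4, 4, 4)
  mask <- full_mask(dims)
  # uniform map -> all ones
  u <- array(2.3, dims)
  m <- normalize_malff(u, mask)
  expect_equal(as.vector(m$data), rep(1, prod(dims)), tolerance = 1e-12)
  # two-voxel mask with ALFF (2, 0) -> mALFF (2, 0)
  m2arr <- array(FALSE, dims); m2arr[1:2, 1, 1] <- TRUE
  mask2 <- brain_mask(m2arr, c(3, 3, 3))
  v <- array(0, dims); v[1, 1, 1] <- 2
  m2 <- normalize_malff(v, mask2)
  expect_equal(m2$data[1:2, 1, 1], c(2, 0))
  # any valid input: mask mean is 1 to near machine precision
  b <- random_bold(dims, 50, seed = 9)
  mm <- normalize_malff(compute_alff(b, mask), mask)
  expect_equal(mean(mm$data[mask$mask]), 1, tolerance = 1e-12)
  # global rescaling of the input series leaves mALFF unchanged
  b2 <- b; b2$data <- b$data * 12.5
  mm2 <- normalize_malff(compute_alff(b2, mask), mask)
  expect_equal(mm2$data, mm$data, tolerance = 1e-10)
  # degenerate all-zero input is rejected
  expect_error(normalize_malff(array(0, dims), mask), "positive")
})

test_that("the subject pipeline rejects bands outside the Nyquist range and mismatched grids", {
  b <- random_bold(c(6, 6, 6), nt = 40)
  mask <- full_mask(c(5, 5, 5))
  expect_error(compute_alff(b, mask), "grid")
  cfg <- pipeline_config(n_dummy = 4)
  m <- malff_pipeline(b, full_mask(c(6, 6, 6)), cfg)
  expect_s3_class(m, "malff_map")
  expect_equal(mean(m$data[full_mask(c(6, 6, 6))$mask]), 1,
               tolerance = 1e-12)
})
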