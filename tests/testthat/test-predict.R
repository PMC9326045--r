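test_that("the feature matrix is one row per subject, one column per labeled voxel", {
  dims <- c(6, 6, 6)
  lab <- array(0L, dims)
  lab[2:3, 2:3, 2] <- 1L
  lab[5, 5, 5] <- 2L
  set.seed(20)
  maps <- lapply(1:4, function(i) array(rnorm(prod(dims)), dims))
  fm <- build_feature_matrix(maps, lab)
  expect_equal(dim(fm$X), c(4, 5))
  # direct lookup oracle: every entry equals the map value at the mapped
  # voxel coordinate
  for (s in 1:4) for (cc in seq_len(ncol(fm$X))) {
    v <- fm$voxels[cc, ]
    expect_identical(fm$X[s, cc], maps[[s]][v$i, v$j, v$k])
  }
  expect_setequal(fm$voxels$label, c(1L, 1L, 1L, 1L, 2L))
  expect_error(build_feature_matrix(maps, array(0L, dims)), "empty")
  expect_error(build_feature_matrix(list(array(0, c(5, 5, 5))), lab), "grid")
})

test_that("the normality check warns on skewed targets and rejects degenerate ones", {
  set.seed(21)
  y <- rnorm(28)
  res <- shapiro_wilk_check(y)
  expect_gt(res$p, 0.05)
  expect_false(res$warned)
  skewed <- exp(rnorm(100))
  expect_warning(res2 <- shapiro_wilk_check(skewed), "normality")
  expect_lt(res2$p, 0.05)
  expect_error(shapiro_wilk_check(c(1, 2)), "at least 3")
  expect_error(shapiro_wilk_check(rep(1, 10)), "constant")
})

test_that("relevance selection keeps correlated columns and honors alpha", {
  set.seed(22)
  n <- 20
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 30), n), zero = rep(1, n))
  expect_warning(sel <- select_features_relevance(X, y, 0.05),
                 "zero-variance")
  expect_true(1 %in% sel)                 # the column equal to y survives
  expect_false(32 %in% sel)               # the constant column never does
  # alpha = 1 selects every finite-variance column
  expect_warning(all_sel <- select_features_relevance(X, y, 1))
  expect_identical(all_sel, 1:31)
  # selection p-values agree with cor.test (oracle on a few columns)
  for (cc in 2:5) {
    p_ref <- cor.test(X[, cc], y)$p.value
    in_sel <- cc %in% suppressWarnings(select_features_relevance(X, y, 0.05))
    expect_identical(in_sel, p_ref < 0.05)
  }
})

test_that("the linear SVR recovers an exact linear rule and degenerates safely", {
  # y = 2x with a tight tube and a large budget: weight ~ 2, intercept ~ 0
  x <- matrix(seq(-1, 1, length.out = 12), ncol = 1)
  fit <- fit_svr(x, 2 * x[, 1], cost = 1e4, epsilon = 0)
  expect_equal(fit$weights, 2, tolerance = 1e-3)
  expect_equal(fit$intercept, 0, tolerance = 1e-3)
  # constant target: flat model at that constant
  fitc <- fit_svr(x, rep(0.7, 12), cost = 1, epsilon = 0.1)
  expect_equal(unname(predict(fitc, matrix(0.3))), 0.7, tolerance = 1e-6)
  # no columns: fallback to the training mean, flagged
  fit0 <- fit_svr(matrix(numeric(0), 5, 0), y = 1:5)
  expect_true(fit0$fallback)
  expect_equal(unname(predict(fit0, matrix(0, 2, 0))), c(3, 3))
  # the primal weights reproduce libsvm's own decision values
  set.seed(23)
  X <- matrix(rnorm(40), 10, 4); y <- rnorm(10)
  fit2 <- fit_svr(X, y, cost = 2, epsilon = 0.05)
  ref <- e1071::svm(X, y, type = "eps-regression", kernel = "linear",
                    cost = 2, epsilon = 0.05, scale = FALSE)
  expect_equal(predict(fit2, X), unname(predict(ref, X)), tolerance = 1e-8)
  # duplicating a non-support training row leaves predictions unchanged
  non_sv <- setdiff(seq_len(10), ref$index)
  if (length(non_sv) > 0) {
    idx <- c(seq_len(10), non_sv[1])
    fit3 <- fit_svr(X[idx, ], y[idx], cost = 2, epsilon = 0.05)
    expect_equal(predict(fit3, X), predict(fit2, X), tolerance = 1e-6)
  }
})

test_that("LOOCV yields one prediction per subject and recovers a planted signal", {
  set.seed(24)
  n <- 28
  signal <- rnorm(n)
  y <- signal + rnorm(n, sd = sd(signal) / sqrt(10))   # SNR 10
  X <- cbind(signal, matrix(rnorm(n * 20), n))
  cv <- loocv_predict(X, y)
  expect_length(cv$predicted, n)
  expect_length(cv$selected_per_fold, n)
  expect_gte(cv$r, 0.9)
  expect_lt(cv$mse, var(y))
  # null features: r hovers near zero on average
  set.seed(25)
  null_r <- replicate(20, {
    Xn <- matrix(rnorm(15 * 30), 15)
    yn <- rnorm(15)
    suppressWarnings(loocv_predict(Xn, yn)$r)
  })
  expect_lt(abs(mean(null_r, na.rm = TRUE)), 0.25)
})

test_that("LOOCV is equivariant under joint subject relabeling", {
  set.seed(26)
  n <- 14
  X <- matrix(rnorm(n * 25), n)
  y <- X[, 1] * 0.5 + rnorm(n, sd = 0.5)
  cv <- loocv_predict(X, y)
  perm <- sample(n)
  cvp <- loocv_predict(X[perm, ], y[perm])
  expect_equal(cvp$predicted, cv$predicted[perm], tolerance = 1e-10)
  expect_equal(cvp$r, cv$r, tolerance = 1e-12)
  expect_equal(cvp$mse, cv$mse, tolerance = 1e-12)
})

test_that("the permutation test counts strict exceedances and labels zero counts", {
  set.seed(27)
  n <- 16
  signal <- rnorm(n)
  y <- signal + rnorm(n, sd = 0.2)
  X <- cbind(signal, matrix(rnorm(n * 10), n))
  cv <- loocv_predict(X, y)
  pn <- permutation_test(X, y, n_permutations = 19, seed = 3, observed = cv)
  expect_length(pn$null_r, 19)
  expect_equal(pn$p_r, sum(pn$null_r > cv$r, na.rm = TRUE) / 19)
  expect_equal(pn$p_mse, sum(pn$null_mse < cv$mse, na.rm = TRUE) / 19)
  if (pn$p_r == 0) expect_match(pn$p_r_label, "^<")
  # permutations are reproducible given the seed
  pn2 <- permutation_test(X, y, n_permutations = 19, seed = 3, observed = cv)
  expect_identical(pn$null_r, pn2$null_r)
  expect_error(permutation_test(X, y, n_permutations = 0), "at least 1")
})

test_that("weight maps normalize to max 1 and summarize clusters", {
  set.seed(28)
  dims <- c(8, 8, 8)
  lab <- array(0L, dims)
  lab[2:3, 2:3, 2:3] <- 1L             # 8 voxels
  lab[6:7, 6:7, 6:7] <- 2L             # 8 voxels
  n <- 20
  latent <- rnorm(n)
  # cluster 1 voxels track the latent almost perfectly; cluster 2 voxels
  # carry the same latent buried in tenfold noise, so they stay weaker even
  # after per-voxel standardization
  maps <- lapply(seq_len(n), function(s) {
    a <- array(rnorm(prod(dims), sd = 0.05), dims)
    a[lab == 1L] <- latent[s] + rnorm(sum(lab == 1L), sd = 0.05)
    a[lab == 2L] <- 0.3 * latent[s] + rnorm(sum(lab == 2L), sd = 0.5)
    a
  })
  y <- latent + rnorm(n, sd = 0.3)
  fm <- build_feature_matrix(maps, lab)
  cl <- structure(list(cluster_mask = lab,
                       clusters = data.frame(label = c(1L, 2L))),
                  class = "cluster_result")
  wm <- compute_weight_map(fm, y, cluster_result = cl)
  expect_equal(max(wm$normalized_weight), 1)
  expect_true(all(wm$normalized_weight >= 0 & wm$normalized_weight <= 1))
  cw <- wm$cluster_weights
  expect_equal(cw$weight[cw$label == 1], 1)   # the stronger ROI peaks at 1
  expect_gt(cw$weight[cw$label == 1], cw$weight[cw$label == 2])
  # the voxel-space volume places weights at the labeled voxels only
  expect_equal(sum(wm$volume != 0), length(wm$selected))
  # a single nonzero weight normalizes to exactly 1
  X1 <- cbind(y + rnorm(n, sd = 1e-3), matrix(rnorm(n * 3), n))
  fm1 <- structure(list(X = X1,
                        voxels = data.frame(column = 1:4, i = 1:4, j = 1,
                                            k = 1, label = 1L)),
                   class = "feature_matrix")
  wm1 <- compute_weight_map(fm1, y, alpha = 1e-12)
  expect_equal(sum(wm1$normalized_weight == 1), 1)
})

test_that("post-hoc cluster correlations match the closed-form Pearson r", {
  set.seed(29)
  dims <- c(6, 6, 6)
  lab <- array(0L, dims); lab[2:4, 2:4, 2] <- 1L
  cl <- structure(list(cluster_mask = lab,
                       clusters = data.frame(label = 1L, sign = 1L,
                                             size_voxels = 9L)),
                  class = "cluster_result")
  n <- 12
  y <- rnorm(n)
  maps <- lapply(seq_len(n), function(s) array(rnorm(prod(dims)), dims))
  out <- posthoc_cluster_correlation(maps, cl, y)
  means <- vapply(maps, function(a) mean(a[lab == 1L]), 0)
  r_oracle <- sum((means - mean(means)) * (y - mean(y))) /
    sqrt(sum((means - mean(means))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)
  expect_equal(out$p, cor.test(means, y)$p.value, tolerance = 1e-12)
  # a cluster whose mean equals y correlates perfectly
  maps2 <- lapply(seq_len(n), function(s) array(y[s], dims))
  out2 <- posthoc_cluster_correlation(maps2, cl, y)
  expect_equal(out2$r, 1, tolerance = 1e-12)
})
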