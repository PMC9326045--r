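# Shared fixtures and independent oracles used across the test files.

# A small cohort configuration used by several tests: 16^3 grid, two
# planted ROIs (one raised, one lowered in patients), short series.
small_cohort_config <- function(seed = 1L, ...) {
  args <- list(
    grid_dims = c(16L, 16L, 16L),
    n_timepoints = 60L,
    n_patients = 8L,
    n_controls = 9L,
    roi_specs = list(roi_spec("up", c(8L, 11L, 8L), 2.5, 0.6),
                     roi_spec("down", c(8L, 5L, 7L), 2.5, -0.6)),
    coupling_rois = c("up", "down"),
    seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

random_bold <- function(dims = c(6L, 6L, 6L), nt = 24L, tr = 2,
                        voxel = c(3, 3, 3), seed = 1L) {
  set.seed(seed)
  bold4d(array(rnorm(prod(dims) * nt), c(dims, nt)), voxel, tr)
}

full_mask <- function(dims = c(6L, 6L, 6L), voxel = c(3, 3, 3)) {
  brain_mask(array(TRUE, dims), voxel)
}

# Independent ALFF oracle: full periodogram through stats::fft (a different
# algorithm from the trig-basis projection in compute_alff), amplitude
# 2|X_k|/N averaged over the closed band.
oracle_alff_series <- function(x, tr, band) {
  n <- length(x)
  xk <- fft(x)
  k <- seq_len(floor(n / 2))
  f <- k / (n * tr)
  sel <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  amp <- 2 * Mod(xk[k + 1]) / n
  mean(amp[sel])
}

# Pooled two-sample t statistic, closed form (equal-variance).
oracle_two_sample_t <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Independent Monte Carlo cluster-size simulation used as the oracle for
# monte_carlo_cluster_threshold at FWHM = 0.  Labeling goes through
# igraph's connected components instead of the package's BFS.
oracle_mc_threshold_white <- function(dims, voxel_p, alpha, n_iter, seed) {
  skip_if_not_installed("igraph")
  set.seed(seed)
  nv <- prod(dims)
  zthr <- qnorm(1 - voxel_p / 2)
  idx <- array(seq_len(nv), dims)
  # edge list of the 6-connected grid graph
  e1 <- cbind(as.vector(idx[-dims[1], , ]), as.vector(idx[-1, , ]))
  e2 <- cbind(as.vector(idx[, -dims[2], ]), as.vector(idx[, -1, ]))
  e3 <- cbind(as.vector(idx[, , -dims[3]]), as.vector(idx[, , -1]))
  edges <- rbind(e1, e2, e3)
  maxsize <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    z <- rnorm(nv)
    z <- (z - mean(z)) / sd(z)
    best <- 0L
    for (sgn in c(1, -1)) {
      sup <- sgn * z > zthr
      if (!any(sup)) next
      keep <- sup[edges[, 1]] & sup[edges[, 2]]
      g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0, nv - igraph::vcount(g)))
      comp <- igraph::components(g)
      sizes <- tabulate(comp$membership[sup], nbins = comp$no)
      best <- max(best, max(sizes))
    }
    maxsize[it] <- best
  }
  k <- 1L
  while (mean(maxsize >= k) > alpha) k <- k + 1L
  k
}

# LOOCV with the relevance filter applied once to ALL subjects before the
# fold split -- the deliberately leaky variant the nested implementation is
# compared against.
leaky_loocv_r <- function(X, y, alpha = 0.05) {
  sel <- suppressWarnings(select_features_relevance(X, y, alpha))
  if (length(sel) == 0L) return(NA_real_)
  Xs <- X[, sel, drop = FALSE]
  n <- nrow(X)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- fit_svr(scale(Xs[-i, , drop = FALSE]),
                   scale(y[-i])[, 1])
    mu <- colMeans(Xs[-i, , drop = FALSE])
    sdv <- apply(Xs[-i, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    xte <- (Xs[i, ] - mu) / sdv
    pred[i] <- predict(fit, matrix(xte, 1)) * sd(y[-i]) + mean(y[-i])
  }
  if (sd(pred) == 0) return(NA_real_)
  cor(pred, y)
}
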