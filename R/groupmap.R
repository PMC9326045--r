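#' Voxel-wise covariate-adjusted group comparison
#'
#' Fits, at every in-mask voxel, the ordinary least squares model
#' `malff ~ intercept + group + covariates` and returns the t statistic and
#' two-sided p value of the group coefficient (positive t = patients >
#' controls).  Covariates are mean-centered before fitting, which leaves
#' the group t unchanged but improves conditioning.
#'
#' @param malff_maps List of `malff_map` objects (or 3D arrays), one per
#'   subject, or a precomputed voxels x subjects matrix.
#' @param group Group labels: a factor/character with patient level `"FSZ"`
#'   vs `"HC"`, or a 0/1 numeric vector (1 = patient).
#' @param covariates Optional subjects x k numeric matrix or data.frame
#'   (e.g. sex as 0/1, age, education); `NULL` for none.
#' @param mask The [brain_mask] shared by the maps.
#' @return A `stat_map`: list with `t` and `p` (3D arrays, `NA` outside the
#'   mask), `df`, and `residuals` (in-mask voxels x subjects matrix, for
#'   smoothness estimation).
#' @export
fit_voxelwise_glm <- function(malff_maps, group, covariates = NULL, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  Y <- if (is.matrix(malff_maps)) malff_maps else stack_maps(malff_maps, mask)
  if (nrow(Y) != mask$n_voxels)
    stop("map matrix rows do not match the mask voxel count")
  n <- ncol(Y)
  g <- encode_group(group, n)
  if (min(table(g)) < 2L) stop("need at least 2 subjects per group")
  D <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n)
      stop("covariates must have one row per subject")
    storage.mode(C) <- "double"
    C <- sweep(C, 2, colMeans(C))
    colnames(C) <- colnames(C) %||% paste0("cov", seq_len(ncol(C)))
    D <- cbind(D, C)
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[setdiff(seq_len(ncol(D)), qrD$pivot[seq_len(qrD$rank)])]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  XtXinv <- chol2inv(chol(crossprod(D)))
  B <- (Y %*% D) %*% XtXinv                      # voxels x p coefficients
  resid <- Y - tcrossprod(B, D)
  df <- n - ncol(D)
  sigma2 <- rowSums(resid^2) / df
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- ifelse(se > 0, B[, 2] / se, 0)         # identical groups -> t = 0
  pval <- 2 * pt(-abs(tval), df)
  tm <- pm <- array(NA_real_, dim = dim(mask$mask))
  tm[mask$mask] <- tval
  pm[mask$mask] <- pval
  structure(list(t = tm, p = pm, df = df, residuals = resid),
            class = "stat_map")
}

encode_group <- function(group, n) {
  if (length(group) != n) stop("`group` length does not match subjects")
  if (is.numeric(group)) {
    if (!all(group %in% c(0, 1))) stop("numeric `group` must be 0/1")
    return(as.numeric(group))
  }
  group <- as.character(group)
  lev <- sort(unique(group))
  if (!setequal(lev, c("FSZ", "HC")) && length(lev) != 2L)
    stop("`group` must have exactly two levels")
  if (setequal(lev, c("FSZ", "HC"))) as.numeric(group == "FSZ")
  else as.numeric(group == lev[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate residual spatial smoothness
#'
#' Per-axis FWHM from the lag-1 spatial autocorrelation of residual maps:
#' `FWHM = voxel_size * sqrt(-2 log(2) / log(rho))`, with `rho` averaged
#' over maps.  This is the standard Gaussian-field estimator feeding the
#' Monte Carlo cluster-size null.  Estimates are clamped below at one voxel
#' width; non-positive correlations yield one voxel width with a warning.
#'
#' @param residual_maps List of 3D residual maps, or an in-mask voxels x
#'   maps matrix (as stored in a `stat_map`).
#' @param mask The [brain_mask].
#' @param voxel_size_mm Length-3 voxel size; defaults to the mask's.
#' @return Numeric length-3 per-axis FWHM in mm (class
#'   `smoothness_estimate`).
#' @export
estimate_smoothness <- function(residual_maps, mask,
                                voxel_size_mm = mask$voxel_size_mm) {
  stopifnot(inherits(mask, "brain_mask"))
  R <- if (is.matrix(residual_maps)) residual_maps else
    stack_maps(residual_maps, mask)
  if (ncol(R) < 2L) stop("need at least 2 residual maps")
  d <- dim(mask$mask)
  keep <- mask$mask
  # For each axis, linear indices of in-mask voxel pairs one voxel apart.
  idx <- array(seq_len(prod(d)), dim = d)
  pair_idx <- function(axis) {
    lo <- hi <- lapply(d, seq_len)
    lo[[axis]] <- seq_len(d[axis] - 1L)
    hi[[axis]] <- 2:d[axis]
    a <- idx[lo[[1]], lo[[2]], lo[[3]]]
    b <- idx[hi[[1]], hi[[2]], hi[[3]]]
    ok <- keep[a] & keep[b]
    cbind(a[ok], b[ok])
  }
  # Map grid linear indices to in-mask row numbers.
  rowmap <- integer(prod(d))
  rowmap[which(keep)] <- seq_len(sum(keep))
  fwhm <- numeric(3)
  for (axis in 1:3) {
    pr <- pair_idx(axis)
    if (nrow(pr) < 10L) {
      warning("too few voxel pairs along axis ", axis,
              "; reporting one voxel width")
      fwhm[axis] <- voxel_size_mm[axis]
      next
    }
    rhos <- vapply(seq_len(ncol(R)), function(m)
      stats::cor(R[rowmap[pr[, 1]], m], R[rowmap[pr[, 2]], m]), 0)
    rho <- mean(rhos)
    if (!is.finite(rho) || rho <= 0) {
      warning("no measurable smoothness along axis ", axis,
              "; reporting one voxel width")
      fwhm[axis] <- voxel_size_mm[axis]
    } else {
      fwhm[axis] <- max(voxel_size_mm[axis],
                        voxel_size_mm[axis] * sqrt(-2 * log(2) / log(rho)))
    }
  }
  structure(fwhm, class = "smoothness_estimate")
}

# Internal: per-sign connected components above threshold; returns sizes of
# each component (positive and negative pooled).
signed_cluster_sizes <- function(z, thr, dims, connectivity) {
  sizes <- integer(0)
  for (sgn in c(1, -1)) {
    sup <- array(sgn * z > thr, dim = dims)
    sup[is.na(sup)] <- FALSE
    lab <- label_components_cpp(as.logical(sup), as.integer(dims),
                                as.integer(connectivity))
    if (max(lab) > 0L) sizes <- c(sizes, tabulate(lab[lab > 0L]))
  }
  sizes
}

#' Monte Carlo cluster-extent threshold
#'
#' Simulates `n_iter` Gaussian noise volumes on the mask, smooths each to
#' the supplied FWHM, standardizes within the mask, applies the two-sided
#' voxel threshold, and records the largest suprathreshold cluster per
#' iteration (positive and negative clusters labeled separately).  Returns
#' the smallest cluster size `k` such that the fraction of iterations whose
#' maximum cluster reaches `k` is at most `alpha`.  This is the AlphaSim
#' procedure that converts an uncorrected voxel p into a minimum cluster
#' extent controlling family-wise error.
#'
#' @param mask A [brain_mask].
#' @param fwhm_mm Noise smoothness: scalar or per-axis length-3 FWHM in mm
#'   (typically the residual estimate from [estimate_smoothness()]).
#' @param voxel_p Two-sided uncorrected voxel p threshold.
#' @param alpha Target family-wise error rate.
#' @param n_iter Number of Monte Carlo iterations (>= 100).
#' @param seed Optional integer seed.
#' @param connectivity 6, 18 or 26.
#' @return Integer minimum cluster size, with attribute `max_sizes` (the
#'   simulated per-iteration maxima).
#' @export
monte_carlo_cluster_threshold <- function(mask, fwhm_mm, voxel_p = 0.001,
                                          alpha = 0.05, n_iter = 1000L,
                                          seed = NULL, connectivity = 6L) {
  stopifnot(inherits(mask, "brain_mask"), voxel_p > 0, voxel_p < 1,
            alpha > 0, alpha <= 1, n_iter >= 100L)
  if (alpha < 1 / n_iter)
    stop(sprintf("alpha = %g is below the 1/%d resolution; increase n_iter",
                 alpha, n_iter))
  if (!is.null(seed)) set.seed(seed)
  fwhm_mm <- rep_len(fwhm_mm, 3L)
  d <- dim(mask$mask)
  keep <- mask$mask
  zthr <- qnorm(1 - voxel_p / 2)
  d4 <- as.integer(c(d, 1L))
  kernels <- lapply(1:3, function(a)
    gaussian_kernel_1d(fwhm_mm[a], mask$voxel_size_mm[a]))
  max_sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    v <- rnorm(prod(d))
    for (a in 1:3)
      if (!is.null(kernels[[a]])) v <- conv_axis_cpp(v, d4, kernels[[a]], a - 1L)
    z <- v[keep]
    z <- (z - mean(z)) / sd(z)
    zfull <- array(NA_real_, dim = d)
    zfull[keep] <- z
    sz <- signed_cluster_sizes(zfull, zthr, d, connectivity)
    max_sizes[it] <- if (length(sz)) max(sz) else 0L
  }
  k <- 1L
  while (mean(max_sizes >= k) > alpha) k <- k + 1L
  structure(k, max_sizes = max_sizes)
}

#' Extract significant clusters from a statistical map
#'
#' Thresholds the voxel-wise map at `p < voxel_p`, partitions
#' suprathreshold voxels by the sign of t, labels connected components per
#' sign, and keeps components of at least `min_cluster_size` voxels.
#' Clusters are canonically ordered by descending size, ties broken by the
#' lexicographic order of the peak coordinate, and relabeled 1..K, so the
#' result is invariant to voxel processing order.
#'
#' @param statmap A `stat_map` from [fit_voxelwise_glm()].
#' @param mask The [brain_mask].
#' @param voxel_p Uncorrected voxel p threshold (strict `<`).
#' @param min_cluster_size Minimum cluster extent in voxels (clusters of
#'   exactly this size are kept).
#' @param connectivity 6, 18 or 26.
#' @return A `cluster_result`: list with `clusters` (data.frame: `label`,
#'   `sign` (+1 = patients > controls), `size_voxels`, `peak_i/j/k`
#'   (1-based voxel indices), `peak_t`), `cluster_mask` (integer label
#'   array, 0 = background), `voxel_p` and `min_cluster_size`.
#' @export
extract_clusters <- function(statmap, mask, voxel_p = 0.001,
                             min_cluster_size = 1L, connectivity = 6L) {
  stopifnot(inherits(statmap, "stat_map"), inherits(mask, "brain_mask"),
            voxel_p > 0, voxel_p < 1, min_cluster_size >= 1L)
  d <- dim(mask$mask)
  sig <- !is.na(statmap$p) & statmap$p < voxel_p & mask$mask
  rows <- list()
  lab_out <- array(0L, dim = d)
  for (sgn in c(1, -1)) {
    sup <- sig & (sgn * statmap$t > 0)
    sup[is.na(sup)] <- FALSE
    lab <- array(label_components_cpp(as.logical(sup), as.integer(d),
                                      as.integer(connectivity)), dim = d)
    nl <- max(lab)
    if (nl == 0L) next
    sizes <- tabulate(lab[lab > 0L], nbins = nl)
    for (l in seq_len(nl)) {
      if (sizes[l] < min_cluster_size) next
      vox <- which(lab == l)
      tv <- statmap$t[vox]
      peak_cand <- vox[abs(tv) == max(abs(tv))]
      peak <- min(peak_cand)      # lexicographic tie-break via linear index
      pc <- arrayInd(peak, d)
      rows[[length(rows) + 1L]] <- list(
        sign = sgn, size_voxels = sizes[l],
        peak_i = pc[1], peak_j = pc[2], peak_k = pc[3],
        peak_t = statmap$t[peak], vox = vox)
    }
  }
  if (length(rows) == 0L) {
    clusters <- data.frame(label = integer(0), sign = integer(0),
                           size_voxels = integer(0), peak_i = integer(0),
                           peak_j = integer(0), peak_k = integer(0),
                           peak_t = numeric(0))
  } else {
    ord <- order(-vapply(rows, `[[`, 0L, "size_voxels"),
                 vapply(rows, `[[`, 0, "peak_i"),
                 vapply(rows, `[[`, 0, "peak_j"),
                 vapply(rows, `[[`, 0, "peak_k"))
    rows <- rows[ord]
    for (l in seq_along(rows)) lab_out[rows[[l]]$vox] <- l
    clusters <- data.frame(
      label = seq_along(rows),
      sign = vapply(rows, `[[`, 0, "sign"),
      size_voxels = vapply(rows, `[[`, 0L, "size_voxels"),
      peak_i = vapply(rows, `[[`, 0, "peak_i"),
      peak_j = vapply(rows, `[[`, 0, "peak_j"),
      peak_k = vapply(rows, `[[`, 0, "peak_k"),
      peak_t = vapply(rows, `[[`, 0, "peak_t"))
  }
  structure(list(clusters = clusters, cluster_mask = lab_out,
                 voxel_p = voxel_p,
                 min_cluster_size = as.integer(min_cluster_size),
                 connectivity = as.integer(connectivity)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), voxel p < %g, min size %d\n",
              nrow(x$clusters), x$voxel_p, x$min_cluster_size))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
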