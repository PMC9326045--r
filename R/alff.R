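#' Pipeline configuration
#'
#' Collects the fixed analysis constants of the pipeline: 10 dummy scans
#' dropped, 0.01-0.08 Hz analysis band, 8-mm FWHM spatial smoothing, 2 mm /
#' 2 degree motion limits, 3 s reaction-time cutoff, relevance-filter alpha
#' 0.05, voxel threshold p < 0.001 with cluster-level alpha 0.05, and 1,000
#' permutations.  All are overridable.
#'
#' @param n_dummy Number of initial dummy scans to discard.
#' @param band_hz Length-2 analysis band (low, high) in Hz.
#' @param smooth_fwhm_mm Spatial smoothing FWHM in mm (0 disables).
#' @param motion_limits Length-2: max translation (mm), max rotation (deg);
#'   subjects must be strictly below both.
#' @param rt_max_s Reaction-time inclusion cutoff in seconds (strict `<`).
#' @param relevance_alpha Two-sided p threshold of the Pearson relevance
#'   filter used for feature selection.
#' @param voxel_p Uncorrected voxel-level p threshold of the group map.
#' @param cluster_alpha Family-wise alpha of the cluster-extent correction.
#' @param n_mc_iter Monte Carlo iterations for the cluster-size null.
#' @param n_permutations Permutations for the prediction significance test.
#' @param svr_cost,svr_epsilon Linear epsilon-SVR hyperparameters;
#'   `svr_cost = NULL` scales C with the feature dimension (see
#'   [fit_svr()]).
#' @param connectivity Cluster connectivity: 6, 18 or 26 neighbors.
#' @param target Phenotype column predicted by the SVR stage.
#' @param seed Integer master seed for all stochastic stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_dummy = 10L,
                            band_hz = c(0.01, 0.08),
                            smooth_fwhm_mm = 8,
                            motion_limits = c(2, 2),
                            rt_max_s = 3,
                            relevance_alpha = 0.05,
                            voxel_p = 0.001,
                            cluster_alpha = 0.05,
                            n_mc_iter = 1000L,
                            n_permutations = 1000L,
                            svr_cost = NULL,
                            svr_epsilon = 0.1,
                            connectivity = 6L,
                            target = "acc_fear",
                            seed = 1L) {
  stopifnot(n_dummy >= 0, length(band_hz) == 2L, band_hz[1] > 0,
            band_hz[2] > band_hz[1], smooth_fwhm_mm >= 0,
            length(motion_limits) == 2L, all(motion_limits > 0),
            rt_max_s > 0, relevance_alpha > 0, relevance_alpha <= 1,
            voxel_p > 0, voxel_p < 1, cluster_alpha > 0, cluster_alpha <= 1,
            n_mc_iter >= 100, n_permutations >= 1,
            is.null(svr_cost) || svr_cost > 0,
            svr_epsilon >= 0, connectivity %in% c(6L, 18L, 26L))
  structure(list(n_dummy = as.integer(n_dummy), band_hz = band_hz,
                 smooth_fwhm_mm = smooth_fwhm_mm,
                 motion_limits = motion_limits, rt_max_s = rt_max_s,
                 relevance_alpha = relevance_alpha, voxel_p = voxel_p,
                 cluster_alpha = cluster_alpha,
                 n_mc_iter = as.integer(n_mc_iter),
                 n_permutations = as.integer(n_permutations),
                 svr_cost = svr_cost, svr_epsilon = svr_epsilon,
                 connectivity = as.integer(connectivity), target = target,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Discard initial dummy scans
#'
#' Scanner equilibration frames at the start of an acquisition are dropped
#' before any analysis; the default pipeline removes the first 10 of the
#' 240 acquired frames.
#'
#' @param bold A [bold4d] object.
#' @param n_dummy Number of leading frames to remove.
#' @return A [bold4d] with `n_timepoints - n_dummy` frames and unchanged
#'   geometry.
#' @export
drop_dummies <- function(bold, n_dummy) {
  stopifnot(inherits(bold, "bold4d"), n_dummy >= 0)
  nt <- n_timepoints(bold)
  if (n_dummy >= nt)
    stop(sprintf("cannot drop %d dummy scans from a %d-frame series",
                 n_dummy, nt))
  if (n_dummy == 0L) return(bold)
  bold$data <- bold$data[, , , (n_dummy + 1L):nt, drop = FALSE]
  bold
}

#' Head-motion quality control
#'
#' A subject passes when maximum translation is strictly below the
#' translation limit (default 2 mm) and maximum rotation strictly below the
#' rotation limit (default 2 degrees).
#'
#' @param max_translation_mm Maximum absolute translation in mm.
#' @param max_rotation_deg Maximum absolute rotation in degrees.
#' @param limits Length-2 numeric `(translation_mm, rotation_deg)`.
#' @return Logical: `TRUE` if the subject passes.
#' @export
#' @examples
#' motion_qc(1.0, 1.0)        # TRUE
#' motion_qc(2.0, 0)          # FALSE: the limit is strict
motion_qc <- function(max_translation_mm, max_rotation_deg,
                      limits = c(2, 2)) {
  stopifnot(length(limits) == 2L, all(limits > 0))
  if (max_translation_mm < 0 || max_rotation_deg < 0)
    stop("motion summaries must be nonnegative")
  (max_translation_mm < limits[1]) && (max_rotation_deg < limits[2])
}

#' Remove a per-voxel linear trend
#'
#' Fits intercept + slope by least squares to each voxel time-series and
#' returns the residuals.
#'
#' @param bold A [bold4d] with at least 3 timepoints.
#' @return A detrended [bold4d]; each voxel's residual mean is ~0.
#' @export
detrend_linear <- function(bold) {
  stopifnot(inherits(bold, "bold4d"))
  nt <- n_timepoints(bold)
  if (nt < 3L) stop("detrending needs at least 3 timepoints")
  tt <- seq_len(nt) - (nt + 1) / 2          # centered time index
  X <- cbind(1, tt)
  M <- bold_matrix(bold)                    # voxels x time
  B <- (M %*% X) %*% chol2inv(chol(crossprod(X)))
  matrix_bold(M - tcrossprod(B, X), bold)
}

# Internal: sampled, normalized 1D Gaussian kernel for one axis.
gaussian_kernel_1d <- function(fwhm_mm, voxel_mm) {
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (sigma_vox < 1e-6) return(NULL)        # effectively identity
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

#' Spatial Gaussian smoothing
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis, scaled by the voxel size.
#' Boundaries are mirrored, so constant fields are conserved.  `fwhm_mm = 0`
#' is the identity.
#'
#' @param x A [bold4d], or a 3D/4D numeric array.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm.
#' @param ... Passed to methods.
#' @return An object of the same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, ...) UseMethod("smooth_gaussian")

#' @rdname smooth_gaussian
#' @export
smooth_gaussian.bold4d <- function(x, fwhm_mm, ...) {
  x$data <- smooth_gaussian(x$data, fwhm_mm, voxel_size_mm = x$voxel_size_mm)
  x
}

#' @rdname smooth_gaussian
#' @param voxel_size_mm Voxel size (array method only).
#' @export
smooth_gaussian.array <- function(x, fwhm_mm, voxel_size_mm, ...) {
  stopifnot(fwhm_mm >= 0, length(voxel_size_mm) == 3L)
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("expected a 3D or 4D array")
  if (fwhm_mm == 0) return(x)
  d4 <- if (nd == 3L) c(dim(x), 1L) else dim(x)
  v <- as.numeric(x)
  for (axis in 0:2) {
    k <- gaussian_kernel_1d(fwhm_mm, voxel_size_mm[axis + 1])
    if (!is.null(k))
      v <- conv_axis_cpp(v, as.integer(d4), k, axis)
  }
  array(v, dim = dim(x))
}

#' Regress nuisance covariates out of a time-series
#'
#' Projects each voxel series onto the orthogonal complement of
#' `[intercept, confounds]` by ordinary least squares.  With no confounds
#' the series is simply mean-centered.
#'
#' @param bold A [bold4d].
#' @param confounds Numeric matrix (timepoints x k), or `NULL` for none.
#' @return A [bold4d] of residuals.
#' @export
regress_nuisance <- function(bold, confounds = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  nt <- n_timepoints(bold)
  if (is.null(confounds)) {
    X <- matrix(1, nt, 1)
  } else {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop(sprintf("confounds have %d rows but the series has %d timepoints",
                   nrow(confounds), nt))
    X <- cbind(1, confounds)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("rank-deficient confound matrix; using pseudo-inverse")
    sv <- svd(X)
    pos <- sv$d > max(sv$d) * 1e-12
    Xp <- sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    M <- bold_matrix(bold)
    return(matrix_bold(M - (M %*% t(Xp)) %*% t(X), bold))
  }
  M <- bold_matrix(bold)
  B <- (M %*% X) %*% chol2inv(chol(crossprod(X)))
  matrix_bold(M - tcrossprod(B, X), bold)
}

# Internal: indices (k) and frequencies of DFT bins inside the closed band.
band_bins <- function(nt, tr_s, band_hz) {
  k <- seq_len(floor(nt / 2))
  f <- k / (nt * tr_s)
  eps <- 1e-9
  sel <- which(f >= band_hz[1] - eps & f <= band_hz[2] + eps)
  list(k = k[sel], f = f[sel])
}

#' Voxel-wise amplitude of low-frequency fluctuation (ALFF)
#'
#' For each in-mask voxel the series is Fourier transformed and the
#' amplitude spectrum averaged over the frequency bins falling in the
#' closed analysis band (default 0.01-0.08 Hz).  The amplitude at bin k is
#' scaled as `2 |X_k| / N`, so a unit-amplitude sinusoid at a bin frequency
#' contributes amplitude 1 at that bin; the scale constant cancels after
#' mALFF normalization.  The series is used at full length with no
#' zero-padding or taper.
#'
#' @param bold A [bold4d], already dummy-dropped and detrended.
#' @param mask A [brain_mask] on the same grid.
#' @param band_hz Closed frequency band (low, high) in Hz; must lie inside
#'   (0, Nyquist).
#' @return An `alff_map`: list with `data` (3D array, `NA` outside the
#'   mask), `band_hz` and `n_bins`.
#' @export
compute_alff <- function(bold, mask, band_hz = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold4d"), inherits(mask, "brain_mask"))
  check_grid(dim(bold$data), mask, "bold")
  nt <- n_timepoints(bold)
  nyq <- 1 / (2 * bold$tr_s)
  if (band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stop("band must satisfy 0 < low < high")
  if (band_hz[2] > nyq)
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz (TR = %g s)",
                 band_hz[2], nyq, bold$tr_s))
  bb <- band_bins(nt, bold$tr_s, band_hz)
  if (length(bb$k) == 0L)
    stop(sprintf(paste0("no DFT bins inside band [%g, %g] Hz with TR = %g s",
                        " and N = %d frames"),
                 band_hz[1], band_hz[2], bold$tr_s, nt))
  M <- bold_matrix(bold)[mask$mask, , drop = FALSE]   # in-mask voxels x time
  ang <- 2 * pi * outer(0:(nt - 1), bb$k) / nt        # time x bins
  re <- M %*% cos(ang)
  im <- M %*% sin(ang)
  amp <- 2 * sqrt(re^2 + im^2) / nt
  vals <- rowMeans(amp)
  out <- array(NA_real_, dim = dim(mask$mask))
  out[mask$mask] <- vals
  structure(list(data = out, band_hz = band_hz, n_bins = length(bb$k)),
            class = "alff_map")
}

#' Normalize ALFF by its global mean (mALFF)
#'
#' Divides every in-mask ALFF value by the mask-wide mean, removing
#' whole-brain amplitude differences between subjects.  The resulting map
#' has in-mask mean exactly 1.
#'
#' @param alff An `alff_map` from [compute_alff()] (or a 3D array).
#' @param mask The [brain_mask] the map was computed on.
#' @return A `malff_map`: list with `data`, `band_hz` and
#'   `normalizing_mean`.
#' @export
normalize_malff <- function(alff, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  a <- if (is.list(alff)) alff$data else alff
  check_grid(dim(a), mask, "ALFF map")
  vals <- a[mask$mask]
  if (anyNA(vals)) stop("ALFF map has NA inside the mask")
  g <- mean(vals)
  if (!is.finite(g) || g <= 0)
    stop("global mean ALFF is not positive; degenerate input")
  out <- array(NA_real_, dim = dim(a))
  out[mask$mask] <- vals / g
  structure(list(data = out,
                 band_hz = if (is.list(alff)) alff$band_hz else NULL,
                 normalizing_mean = g),
            class = "malff_map")
}

#' Single-subject mALFF pipeline
#'
#' Applies the subject-level preprocessing in the pipeline's canonical
#' order -- drop dummy scans, detrend, spatially smooth, optional nuisance
#' regression -- then computes ALFF and normalizes it to mALFF.
#'
#' @param bold A raw [bold4d].
#' @param mask A [brain_mask].
#' @param config A [pipeline_config()].
#' @param confounds Optional timepoints x k nuisance matrix (rows must
#'   match the post-dummy series length).
#' @return A `malff_map`.
#' @export
malff_pipeline <- function(bold, mask, config = pipeline_config(),
                           confounds = NULL) {
  b <- drop_dummies(bold, config$n_dummy)
  b <- detrend_linear(b)
  if (config$smooth_fwhm_mm > 0)
    b <- smooth_gaussian(b, config$smooth_fwhm_mm)
  if (!is.null(confounds))
    b <- regress_nuisance(b, confounds)
  normalize_malff(compute_alff(b, mask, config$band_hz), mask)
}
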