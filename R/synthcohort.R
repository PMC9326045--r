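#' Spherical region-of-interest specification
#'
#' Defines a spherical ROI in voxel coordinates with a planted group effect
#' on in-band oscillation amplitude (patients relative to controls, in
#' units of the baseline amplitude).
#'
#' @param name ROI name.
#' @param center_voxel Length-3 integer voxel center (1-based).
#' @param radius_voxels Sphere radius in voxels.
#' @param group_effect Signed amplitude increase for patients vs controls,
#'   as a fraction of the baseline amplitude.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(name, center_voxel, radius_voxels, group_effect) {
  stopifnot(is.character(name), length(center_voxel) == 3L,
            radius_voxels > 0, is.numeric(group_effect))
  structure(list(name = name, center_voxel = as.integer(center_voxel),
                 radius_voxels = radius_voxels, group_effect = group_effect),
            class = "roi_spec")
}

# Default planted ROIs for the 24^3 demonstration grid: a posterior-midline
# sphere with raised amplitude in patients (posterior cingulate/precuneus
# analogue), an occipital sphere with lowered amplitude (calcarine
# analogue), and a sensorimotor sphere with lowered amplitude that does not
# drive behavior.
default_rois <- function() {
  list(
    roi_spec("pcc_precuneus", c(12L, 16L, 12L), 3.0,  0.6),
    roi_spec("calcarine",     c(12L,  6L, 10L), 3.0, -0.6),
    roi_spec("motor",         c( 7L, 12L, 16L), 2.5, -0.5)
  )
}

#' Synthetic cohort configuration
#'
#' Defines the generative model of the synthetic resting-state cohort: two
#' groups (default 28 patients, 33 controls), spatially smoothed Gaussian
#' noise volumes carrying band-limited (0.01-0.08 Hz) sinusoidal
#' oscillations inside spherical ROIs, group differences in oscillation
#' amplitude, and a fearful-recognition accuracy score linearly coupled to
#' the shared amplitude deviation of the coupling ROIs.  Default behavioral
#' means and spreads follow the cohort description (fearful accuracy
#' 0.74 patients / 0.86 controls; happy 0.89 / 0.94).
#'
#' @param grid_dims Length-3 integer grid (all >= 8).
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_timepoints Acquired frames per subject (includes dummy scans).
#' @param n_patients,n_controls Group sizes.
#' @param noise_fwhm_mm Spatial FWHM of the noise field (0 = white).
#' @param noise_sd Noise standard deviation per voxel and frame (signal
#'   units), after spatial smoothing.
#' @param base_band_amp Baseline amplitude of each planted in-band sinusoid.
#' @param n_sinusoids Sinusoids summed per ROI and subject.
#' @param roi_specs List of [roi_spec()] objects.
#' @param coupling_rois Names of the ROIs whose shared amplitude deviation
#'   drives fearful accuracy; must be a subset of `roi_specs` names.
#' @param coupling_slope Accuracy units per amplitude unit.
#' @param latent_sd SD of the per-subject latent amplitude deviation
#'   (fraction of baseline amplitude).  Coupling ROIs share one latent per
#'   subject; other ROIs draw independent latents.
#' @param behavior_noise_sd SD of the accuracy noise on the fearful score.
#' @param happy_noise_sd SD of the accuracy noise on the happy score (not
#'   brain-coupled).
#' @param acc_fear_mean,acc_happy_mean Named length-2 vectors (`FSZ`, `HC`)
#'   of group mean accuracies.
#' @param seed Integer seed; identical configurations generate
#'   byte-identical cohorts.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(grid_dims = c(24L, 24L, 24L),
                         voxel_size_mm = c(3, 3, 3),
                         tr_s = 2,
                         n_timepoints = 240L,
                         n_patients = 28L,
                         n_controls = 33L,
                         noise_fwhm_mm = 6,
                         noise_sd = 1,
                         base_band_amp = 1,
                         n_sinusoids = 3L,
                         roi_specs = default_rois(),
                         coupling_rois = c("pcc_precuneus", "calcarine"),
                         coupling_slope = 0.28,
                         latent_sd = 0.25,
                         behavior_noise_sd = 0.07,
                         happy_noise_sd = 0.06,
                         acc_fear_mean = c(FSZ = 0.74, HC = 0.86),
                         acc_happy_mean = c(FSZ = 0.89, HC = 0.94),
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 8L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            tr_s > 0, n_timepoints >= 2L, n_patients >= 1L, n_controls >= 1L,
            noise_fwhm_mm >= 0, noise_sd > 0, base_band_amp >= 0,
            n_sinusoids >= 1L, latent_sd >= 0, behavior_noise_sd >= 0,
            happy_noise_sd >= 0)
  roi_names <- vapply(roi_specs, `[[`, "", "name")
  if (anyDuplicated(roi_names)) stop("ROI names must be unique")
  if (!all(coupling_rois %in% roi_names))
    stop("`coupling_rois` must be a subset of the ROI names: missing ",
         paste(setdiff(coupling_rois, roi_names), collapse = ", "))
  structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                 tr_s = tr_s, n_timepoints = as.integer(n_timepoints),
                 n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 noise_fwhm_mm = noise_fwhm_mm, noise_sd = noise_sd,
                 base_band_amp = base_band_amp,
                 n_sinusoids = as.integer(n_sinusoids),
                 roi_specs = roi_specs, coupling_rois = coupling_rois,
                 coupling_slope = coupling_slope, latent_sd = latent_sd,
                 behavior_noise_sd = behavior_noise_sd,
                 happy_noise_sd = happy_noise_sd,
                 acc_fear_mean = acc_fear_mean,
                 acc_happy_mean = acc_happy_mean,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Ellipsoidal brain mask inscribed in a grid
#'
#' The synthetic "brain" is the set of voxels inside the ellipsoid
#' inscribed in the grid, which avoids shipping an atlas while still giving
#' the mask a curved boundary.
#'
#' @param grid_dims Length-3 integer grid.
#' @param voxel_size_mm Length-3 voxel size in mm.
#' @return A [brain_mask].
#' @export
ellipsoid_mask <- function(grid_dims, voxel_size_mm = c(3, 3, 3)) {
  d <- as.integer(grid_dims)
  ctr <- (d + 1) / 2
  semi <- d / 2 - 0.5
  i <- (seq_len(d[1]) - ctr[1]) / semi[1]
  j <- (seq_len(d[2]) - ctr[2]) / semi[2]
  k <- (seq_len(d[3]) - ctr[3]) / semi[3]
  m <- outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
  brain_mask(m, voxel_size_mm)
}

# Internal: logical 3D array of voxels inside an ROI sphere.
roi_voxel_mask <- function(roi, grid_dims) {
  d <- as.integer(grid_dims)
  i <- seq_len(d[1]) - roi$center_voxel[1]
  j <- seq_len(d[2]) - roi$center_voxel[2]
  k <- seq_len(d[3]) - roi$center_voxel[3]
  outer(outer(i^2, j^2, `+`), k^2, `+`) <= roi$radius_voxels^2
}

# Internal: validate that every ROI sphere lies fully inside the mask.
check_rois_in_mask <- function(config, mask) {
  for (roi in config$roi_specs) {
    rm <- roi_voxel_mask(roi, config$grid_dims)
    if (sum(rm) == 0L)
      stop(sprintf("ROI '%s' contains no voxels", roi$name))
    if (any(rm & !mask$mask))
      stop(sprintf("ROI '%s' extends outside the brain mask", roi$name))
  }
  invisible(TRUE)
}

# Internal: variance-preservation factor of separable Gaussian smoothing of
# white noise (interior voxels): the smoothed field's variance is the
# product over axes of sum(kernel^2).
smoothing_var_factor <- function(fwhm_mm, voxel_size_mm) {
  f <- 1
  for (a in 1:3) {
    k <- gaussian_kernel_1d(fwhm_mm, voxel_size_mm[a])
    if (!is.null(k)) f <- f * sum(k^2)
  }
  f
}

# Internal: draw phenotypes and per-subject, per-ROI amplitude multipliers.
# Called under the cohort seed.  Returns the phenotype table plus the
# latent structure the volumes are generated from.
synth_phenotypes <- function(config) {
  n <- config$n_patients + config$n_controls
  group <- rep(c("FSZ", "HC"), c(config$n_patients, config$n_controls))
  is_pat <- as.numeric(group == "FSZ")
  sex <- ifelse(runif(n) < ifelse(is_pat == 1, 0.571, 0.485), "M", "F")
  age <- round(pmin(50, pmax(18, rnorm(n,
    mean = ifelse(is_pat == 1, 25.1, 24.2),
    sd = ifelse(is_pat == 1, 6.9, 5.0)))), 1)
  education <- round(pmin(20, pmax(6, rnorm(n,
    mean = ifelse(is_pat == 1, 11.3, 11.7),
    sd = ifelse(is_pat == 1, 3.3, 3.1)))), 1)

  roi_names <- vapply(config$roi_specs, `[[`, "", "name")
  effects <- vapply(config$roi_specs, `[[`, 0, "group_effect")
  is_coupling <- roi_names %in% config$coupling_rois
  latent_c <- rnorm(n, 0, config$latent_sd)      # shared across coupling ROIs
  latents <- matrix(NA_real_, n, length(roi_names),
                    dimnames = list(NULL, roi_names))
  for (r in seq_along(roi_names)) {
    latents[, r] <- if (is_coupling[r]) latent_c else
      rnorm(n, 0, config$latent_sd)
  }
  # Amplitude multiplier per subject and ROI, floored at zero.
  amp <- 1 + outer(is_pat, effects) + latents
  amp[amp < 0] <- 0
  colnames(amp) <- roi_names

  clip01 <- function(x) pmin(1, pmax(0, x))
  acc_fear <- clip01(config$acc_fear_mean[group] +
                       config$coupling_slope * config$base_band_amp * latent_c +
                       rnorm(n, 0, config$behavior_noise_sd))
  acc_happy <- clip01(config$acc_happy_mean[group] +
                        rnorm(n, 0, config$happy_noise_sd))
  pheno <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = group, sex = sex, age = age, education = education,
    acc_happy = as.numeric(acc_happy), acc_fear = as.numeric(acc_fear),
    stringsAsFactors = FALSE)
  list(pheno = pheno, amp = amp, latent_c = latent_c)
}

# Internal: generate one subject's 4D volume given the subject's per-ROI
# amplitude multipliers.  Deterministic given `seed`.
synth_bold <- function(config, amp_row, seed) {
  set.seed(seed)
  d <- config$grid_dims
  nt <- config$n_timepoints
  noise <- array(gauss_noise_cpp(prod(d) * nt, seed), dim = c(d, nt))
  if (config$noise_fwhm_mm > 0) {
    noise <- smooth_gaussian(noise, config$noise_fwhm_mm,
                             voxel_size_mm = config$voxel_size_mm)
    noise <- noise / sqrt(smoothing_var_factor(config$noise_fwhm_mm,
                                               config$voxel_size_mm))
  }
  M <- matrix(noise, nrow = prod(d), ncol = nt) * config$noise_sd
  tt <- (seq_len(nt) - 1) * config$tr_s
  for (roi in config$roi_specs) {
    rm <- which(roi_voxel_mask(roi, d))
    freqs <- runif(config$n_sinusoids, 0.01, 0.08)
    phases <- runif(config$n_sinusoids, 0, 2 * pi)
    sig <- rep(0, nt)
    for (s in seq_len(config$n_sinusoids))
      sig <- sig + sin(2 * pi * freqs[s] * tt + phases[s])
    a <- config$base_band_amp * amp_row[[roi$name]]
    M[rm, ] <- M[rm, ] + rep(1, length(rm)) %o% (a * sig)
  }
  bold4d(array(M, dim = c(d, nt)), config$voxel_size_mm, config$tr_s)
}

#' Generate a synthetic resting-state cohort
#'
#' Draws phenotypes (group, sex, age, education, happy/fearful accuracy)
#' and one 4D BOLD volume per subject.  Each voxel series is spatially
#' smoothed Gaussian noise; inside each ROI a sum of sinusoids at random
#' in-band frequencies is added whose amplitude is
#' `base_band_amp * (1 + group_effect * is_patient + subject_latent)`.
#' Fearful accuracy is linearly coupled to the latent shared by the
#' coupling ROIs.  Identical configurations (including the seed) produce
#' bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list with `bold` (list of [bold4d], one per subject),
#'   `phenotypes` (data.frame), `mask` ([brain_mask]) and `truth`
#'   (the [ground_truth_report()] plus the realized per-subject latents).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  mask <- ellipsoid_mask(config$grid_dims, config$voxel_size_mm)
  check_rois_in_mask(config, mask)
  set.seed(config$seed)
  ph <- synth_phenotypes(config)
  bold <- lapply(seq_len(nrow(ph$pheno)), function(i) {
    synth_bold(config, ph$amp[i, , drop = TRUE],
               stage_seed(config$seed, paste0("bold_", i)))
  })
  names(bold) <- ph$pheno$subject_id
  truth <- ground_truth_report(config)
  truth$subject_amplitude <- ph$amp
  truth$latent_coupling <- ph$latent_c
  list(bold = bold, phenotypes = ph$pheno, mask = mask, truth = truth)
}

#' Report the effects planted by a configuration
#'
#' Returns the ROI voxel masks, the true group amplitude effects and the
#' true behavioral coupling weights, for use by recovery tests.
#'
#' @param config A [synth_config()].
#' @return A list with `mask`, `roi_masks` (named list of logical arrays),
#'   `group_effects` and `coupling_weights` (named numeric vectors).
#' @export
ground_truth_report <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  roi_names <- vapply(config$roi_specs, `[[`, "", "name")
  roi_masks <- lapply(config$roi_specs, roi_voxel_mask, config$grid_dims)
  names(roi_masks) <- roi_names
  effects <- vapply(config$roi_specs, `[[`, 0, "group_effect")
  names(effects) <- roi_names
  coupling <- ifelse(roi_names %in% config$coupling_rois,
                     config$coupling_slope, 0)
  names(coupling) <- roi_names
  list(mask = ellipsoid_mask(config$grid_dims, config$voxel_size_mm),
       roi_masks = roi_masks, group_effects = effects,
       coupling_weights = coupling)
}

#' Simulate a visual-search trial log for one subject
#'
#' Emulates the emotional face search task: blocks of trials showing 2 or 4
#' faces, the emotional target present in half the trials (default 6 blocks
#' of 40 trials).  Correctness is Bernoulli with the subject's true
#' accuracy; reaction times are log-normal with a configurable fraction of
#' trials exceeding the 3-second cutoff.
#'
#' @param subject_accuracy True probability of a correct response.
#' @param subject_id Subject identifier recorded in the log.
#' @param condition `"happy"` or `"fearful"`.
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block (must be even).
#' @param rt_model List with `meanlog` (log of the median RT in ms) and
#'   `tail_prob` (target fraction of trials with RT >= 3,000 ms; 0 gives
#'   every trial the median RT).
#' @param seed Integer seed.
#' @return A data.frame with columns `subject_id`, `condition`, `set_size`,
#'   `target_present`, `response` (`"target"`/`"no-target"`) and `rt_ms`.
#' @export
#' @examples
#' log <- make_trial_log(0.86, seed = 1)
#' nrow(log)  # 6 blocks x 40 trials = 240
make_trial_log <- function(subject_accuracy, subject_id = "sub-001",
                           condition = "fearful", n_blocks = 6L,
                           trials_per_block = 40L,
                           rt_model = list(meanlog = log(1000),
                                           tail_prob = 0.02),
                           seed = 1L) {
  stopifnot(subject_accuracy >= 0, subject_accuracy <= 1,
            condition %in% c("happy", "fearful"),
            n_blocks >= 1L, trials_per_block >= 2L,
            trials_per_block %% 2L == 0L,
            rt_model$tail_prob >= 0, rt_model$tail_prob < 0.5)
  set.seed(seed)
  n <- n_blocks * trials_per_block
  target_present <- as.vector(vapply(seq_len(n_blocks), function(b)
    sample(rep(c(TRUE, FALSE), trials_per_block / 2)),
    logical(trials_per_block)))
  set_size <- as.vector(vapply(seq_len(n_blocks), function(b)
    sample(rep(c(2L, 4L), trials_per_block / 2)),
    integer(trials_per_block)))
  correct <- rbinom(n, 1, subject_accuracy) == 1
  response <- ifelse(correct == target_present, "target", "no-target")
  rt_cut <- log(3000)
  sdlog <- if (rt_model$tail_prob <= 0) 0 else
    (rt_cut - rt_model$meanlog) / qnorm(1 - rt_model$tail_prob)
  if (sdlog < 0)
    stop("rt_model meanlog at or above the 3 s cutoff requires tail_prob > 0.5")
  rt_ms <- if (sdlog == 0) rep(exp(rt_model$meanlog), n) else
    rlnorm(n, rt_model$meanlog, sdlog)
  data.frame(subject_id = subject_id, condition = condition,
             set_size = set_size, target_present = target_present,
             response = response, rt_ms = rt_ms, stringsAsFactors = FALSE)
}
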