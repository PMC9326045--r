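#' Combined pipeline + cohort configuration
#'
#' Bundles a [synth_config()] (the simulated cohort) with a
#' [pipeline_config()] (the analysis constants) for [run_all()].
#'
#' @param synth A [synth_config()].
#' @param pipeline A [pipeline_config()].
#' @return A list of class `ferpredict_config`.
#' @export
ferpredict_config <- function(synth = synth_config(),
                              pipeline = pipeline_config()) {
  stopifnot(inherits(synth, "synth_config"),
            inherits(pipeline, "pipeline_config"))
  structure(list(synth = synth, pipeline = pipeline),
            class = "ferpredict_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys `synth:` and `pipeline:` override the corresponding
#' defaults of [synth_config()] and [pipeline_config()]; `rois:` (a list of
#' `name`/`center_voxel`/`radius_voxels`/`group_effect` entries) replaces
#' the default planted ROIs.
#'
#' @param path YAML file path.
#' @return A `ferpredict_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  sargs <- y$synth %||% list()
  if (!is.null(y$rois)) {
    sargs$roi_specs <- lapply(y$rois, function(r)
      roi_spec(r$name, unlist(r$center_voxel), r$radius_voxels,
               r$group_effect))
  }
  pargs <- y$pipeline %||% list()
  ferpredict_config(do.call(synth_config, sargs),
                    do.call(pipeline_config, pargs))
}

#' Generate a cohort and compute every subject's mALFF map
#'
#' Streams subjects one at a time (generate the 4D volume, run the
#' subject-level [malff_pipeline()], discard the volume) so that cohorts at
#' full length fit comfortably in memory.
#'
#' @param config A [synth_config()].
#' @param pipeline A [pipeline_config()].
#' @return A list with `malff` (named list of `malff_map`), `phenotypes`,
#'   `mask` and `truth`.
#' @export
cohort_malff <- function(config, pipeline = pipeline_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_timepoints <= pipeline$n_dummy)
    stop("n_timepoints must exceed the number of dummy scans")
  mask <- ellipsoid_mask(config$grid_dims, config$voxel_size_mm)
  check_rois_in_mask(config, mask)
  set.seed(config$seed)
  ph <- synth_phenotypes(config)
  malff <- lapply(seq_len(nrow(ph$pheno)), function(i) {
    b <- synth_bold(config, ph$amp[i, , drop = TRUE],
                    stage_seed(config$seed, paste0("bold_", i)))
    malff_pipeline(b, mask, pipeline)
  })
  names(malff) <- ph$pheno$subject_id
  truth <- ground_truth_report(config)
  truth$subject_amplitude <- ph$amp
  truth$latent_coupling <- ph$latent_c
  list(malff = malff, phenotypes = ph$pheno, mask = mask, truth = truth)
}

#' Run the full pipeline end to end
#'
#' Simulate (or accept) a cohort, compute mALFF per subject, map
#' covariate-adjusted group differences with Monte Carlo cluster-extent
#' correction, and run the relevance-filtered LOOCV SVR prediction with
#' permutation inference on the patient group.  Writes predictions, the
#' cluster table, null distributions, a summary JSON and a run manifest to
#' `out_dir`.  All stage seeds derive deterministically from `seed`, so a
#' rerun with the same configuration reproduces identical outputs.
#'
#' @param config A `ferpredict_config` (or [synth_config()], paired with
#'   default pipeline settings).
#' @param out_dir Output directory.
#' @param seed Master seed; overrides the seed in the synthetic config.
#' @param write_volumes If `TRUE`, write per-subject mALFF maps, the t map,
#'   the cluster mask and the weight map as NIfTI files.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_all <- function(config, out_dir, seed = NULL, write_volumes = FALSE,
                    verbose = TRUE) {
  if (inherits(config, "synth_config"))
    config <- ferpredict_config(synth = config)
  stopifnot(inherits(config, "ferpredict_config"))
  sc <- config$synth
  pc <- config$pipeline
  if (!is.null(seed)) {
    sc$seed <- as.integer(seed)
    pc$seed <- as.integer(seed)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(tic() - t0, 2)
    say("[%s] done in %.1f s", name, timings[[name]])
    r
  }

  # -- simulate + alff -------------------------------------------------
  cm <- stage("simulate+alff", cohort_malff(sc, pc))
  pheno <- validate_phenotypes(cm$phenotypes)
  write.csv(pheno, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)

  # -- behavior --------------------------------------------------------
  behavior <- stage("behavior", {
    logs <- do.call(rbind, lapply(seq_len(nrow(pheno)), function(i) {
      rbind(make_trial_log(pheno$acc_happy[i], pheno$subject_id[i], "happy",
                           seed = stage_seed(pc$seed, paste0("th", i))),
            make_trial_log(pheno$acc_fear[i], pheno$subject_id[i], "fearful",
                           seed = stage_seed(pc$seed, paste0("tf", i))))
    }))
    acc <- score_accuracy(logs, rt_max_s = pc$rt_max_s)
    list(accuracy = acc, summary = summarize_groups(acc, pheno))
  })
  write.csv(behavior$accuracy, file.path(out_dir, "accuracy.csv"),
            row.names = FALSE)

  # -- groupmap --------------------------------------------------------
  gm <- stage("groupmap", {
    covars <- cbind(sex = as.numeric(pheno$sex == "M"), age = pheno$age,
                    education = pheno$education)
    sm <- fit_voxelwise_glm(cm$malff, pheno$group, covars, cm$mask)
    fwhm <- estimate_smoothness(sm$residuals, cm$mask)
    k_min <- monte_carlo_cluster_threshold(
      cm$mask, as.numeric(fwhm), voxel_p = pc$voxel_p,
      alpha = pc$cluster_alpha, n_iter = pc$n_mc_iter,
      seed = stage_seed(pc$seed, "mc"), connectivity = pc$connectivity)
    cl <- extract_clusters(sm, cm$mask, pc$voxel_p, k_min, pc$connectivity)
    list(statmap = sm, fwhm = fwhm, min_cluster_size = as.integer(k_min),
         clusters = cl)
  })
  write.csv(gm$clusters$clusters, file.path(out_dir, "clusters.csv"),
            row.names = FALSE)

  # -- predict ---------------------------------------------------------
  pred <- NULL
  if (nrow(gm$clusters$clusters) > 0L) {
    pred <- stage("predict", {
      pat <- pheno$group == "FSZ"
      y <- pheno[[pc$target]][pat]
      fm <- build_feature_matrix(cm$malff[pat], gm$clusters,
                                 subject_ids = pheno$subject_id[pat])
      swc <- tryCatch(suppressWarnings(shapiro_wilk_check(y)),
                      error = function(e) list(statistic = NA, p = NA,
                                               warned = NA))
      cv <- loocv_predict(fm, y, alpha = pc$relevance_alpha,
                          cost = pc$svr_cost, epsilon = pc$svr_epsilon)
      pn <- permutation_test(fm, y, n_permutations = pc$n_permutations,
                             alpha = pc$relevance_alpha, cost = pc$svr_cost,
                             epsilon = pc$svr_epsilon,
                             seed = stage_seed(pc$seed, "perm"),
                             observed = cv)
      wm <- compute_weight_map(fm, y, alpha = pc$relevance_alpha,
                               cost = pc$svr_cost, epsilon = pc$svr_epsilon,
                               cluster_result = gm$clusters)
      ph_cor <- posthoc_cluster_correlation(cm$malff[pat], gm$clusters, y)
      list(features = fm, shapiro = swc, cv = cv, null = pn, weights = wm,
           cluster_correlations = ph_cor)
    })
    write.csv(data.frame(subject_id = rownames(pred$features$X),
                         actual = pred$cv$actual,
                         predicted = pred$cv$predicted),
              file.path(out_dir, "predictions.csv"), row.names = FALSE)
    write.csv(data.frame(null_r = pred$null$null_r,
                         null_mse = pred$null$null_mse),
              file.path(out_dir, "null_distribution.csv"), row.names = FALSE)
    cw <- pred$weights$cluster_weights
    names(cw)[names(cw) == "weight"] <- "svr_weight"
    rep_df <- merge(pred$cluster_correlations, cw, by = "label")
    write.csv(rep_df[, c("label", "sign", "size_voxels", "svr_weight",
                         "r", "p")],
              file.path(out_dir, "cluster_report.csv"), row.names = FALSE)
  } else {
    say("[predict] skipped: no significant clusters")
  }

  if (write_volumes) {
    for (id in names(cm$malff))
      write_volume(cm$malff[[id]],
                   file.path(out_dir, paste0(id, "_malff.nii.gz")),
                   voxel_size_mm = sc$voxel_size_mm)
    tmap <- gm$statmap$t
    attr(tmap, "voxel_size_mm") <- sc$voxel_size_mm
    write_volume(tmap, file.path(out_dir, "tmap.nii.gz"))
    labm <- gm$clusters$cluster_mask + 0
    attr(labm, "voxel_size_mm") <- sc$voxel_size_mm
    write_volume(labm, file.path(out_dir, "cluster_mask.nii.gz"))
    if (!is.null(pred)) {
      wv <- pred$weights$volume
      attr(wv, "voxel_size_mm") <- sc$voxel_size_mm
      write_volume(wv, file.path(out_dir, "weight_map.nii.gz"))
    }
    write_volume(cm$mask, file.path(out_dir, "mask.nii.gz"))
  }

  summary <- list(
    n_patients = sum(pheno$group == "FSZ"),
    n_controls = sum(pheno$group == "HC"),
    target = pc$target,
    min_cluster_size = gm$min_cluster_size,
    residual_fwhm_mm = round(as.numeric(gm$fwhm), 3),
    n_clusters = nrow(gm$clusters$clusters),
    n_mask_voxels = sum(gm$clusters$cluster_mask > 0),
    behavior = behavior$summary,
    shapiro_p = if (!is.null(pred)) pred$shapiro$p else NA,
    r = if (!is.null(pred)) pred$cv$r else NA,
    mse = if (!is.null(pred)) pred$cv$mse else NA,
    p_r = if (!is.null(pred)) pred$null$p_r else NA,
    p_r_label = if (!is.null(pred)) pred$null$p_r_label else NA,
    p_mse = if (!is.null(pred)) pred$null$p_mse else NA,
    p_mse_label = if (!is.null(pred)) pred$null$p_mse_label else NA,
    n_selected_per_fold = if (!is.null(pred))
      range(lengths(pred$cv$selected_per_fold)) else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "ferpredict",
    version = as.character(packageVersion("ferpredict")),
    created = format(Sys.time(), tz = "UTC"),
    seed = pc$seed,
    synth_seed = sc$seed,
    config = list(synth = unclass_config(sc), pipeline = unclass(pc)),
    stage_seconds = as.list(timings),
    outputs = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE))))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  manifest$outputs$manifest.json <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cm, behavior = behavior, groupmap = gm,
                 predict = pred, summary = summary, manifest = manifest))
}

# Internal: serializable form of a synth_config (ROIs as plain lists).
unclass_config <- function(sc) {
  out <- unclass(sc)
  out$roi_specs <- lapply(out$roi_specs, unclass)
  out
}
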