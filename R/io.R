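#' Read a NIfTI-1 volume
#'
#' Reads a 4D file into a [bold4d] (voxel size and TR taken from the
#' header's pixdim) or a 3D file into a plain array with a `voxel_size_mm`
#' attribute.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param expect `"any"`, `"bold"` (error unless 4D) or `"map"` (error
#'   unless 3D).
#' @return A [bold4d] or a 3D numeric array.
#' @export
read_volume <- function(path, expect = c("any", "bold", "map")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd == 4L) {
    if (expect == "map")
      stop(path, " is 4D but a 3D map was expected")
    tr <- RNifti::pixdim(img)[4]
    pd3 <- RNifti::pixdim(img)[1:3]
    if (!is.finite(tr) || tr <= 0)
      stop(path, " has no usable TR in its header (pixdim[4])")
    return(bold4d(array(as.numeric(img), dim = dim(img)), pd3, tr))
  }
  if (nd == 3L) {
    if (expect == "bold")
      stop(path, " is 3D but a 4D time-series was expected")
    out <- array(as.numeric(img), dim = dim(img))
    attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1:3]
    return(out)
  }
  stop(path, " has ", nd, " dimensions; expected 3 or 4")
}

#' Write a volume as NIfTI-1
#'
#' Writes a [bold4d] (4D, TR stored in pixdim), a `brain_mask`, an
#' `alff_map`/`malff_map`, or a bare 3D array.  Data are stored as
#' double-precision floats so round trips are bit-identical.
#'
#' @param x The object to write.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Required for bare arrays without a `voxel_size_mm`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, voxel_size_mm = NULL) {
  if (inherits(x, "bold4d")) {
    img <- RNifti::asNifti(x$data)
    RNifti::pixdim(img) <- c(x$voxel_size_mm, x$tr_s)
  } else {
    a <- if (inherits(x, "brain_mask")) x$mask + 0 else
      if (is.list(x) && !is.null(x$data)) x$data else x
    vs <- voxel_size_mm %||% attr(x, "voxel_size_mm") %||%
      (if (inherits(x, "brain_mask")) x$voxel_size_mm else NULL)
    if (is.null(vs)) stop("voxel_size_mm is required to write a bare array")
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- vs
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and validate a phenotype table
#'
#' The table must contain `subject_id`, `group` (`FSZ`/`HC`), `sex`, `age`,
#' `education`, `acc_happy`, `acc_fear`; subject ids must be unique and
#' accuracies in `[0, 1]`.
#'
#' @param path CSV path.
#' @return A validated data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ph <- read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(ph)
}

#' @rdname read_phenotypes
#' @param phenotypes A data.frame to validate in place.
#' @export
validate_phenotypes <- function(phenotypes) {
  need <- c("subject_id", "group", "sex", "age", "education",
            "acc_happy", "acc_fear")
  missing_cols <- setdiff(need, names(phenotypes))
  if (length(missing_cols))
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(phenotypes$subject_id))
    stop("duplicate subject_id values in phenotype table")
  if (!all(phenotypes$group %in% c("FSZ", "HC")))
    stop("group must be 'FSZ' or 'HC'; found: ",
         paste(setdiff(unique(phenotypes$group), c("FSZ", "HC")),
               collapse = ", "))
  for (col in c("acc_happy", "acc_fear")) {
    v <- phenotypes[[col]]
    if (anyNA(v) || any(v < 0 | v > 1))
      stop(col, " must lie in [0, 1] with no missing values")
  }
  phenotypes
}

#' Read a brain mask from NIfTI-1
#'
#' @param path Path to a 3D mask volume (nonzero = in mask).
#' @return A [brain_mask].
#' @export
read_mask <- function(path) {
  a <- read_volume(path, expect = "map")
  brain_mask(a != 0, attr(a, "voxel_size_mm"))
}

#' Write the cohort produced by [make_cohort()] to disk
#'
#' Writes one 4D NIfTI per subject, the brain mask, the phenotype CSV and
#' (optionally) per-subject trial logs.
#'
#' @param cohort A list from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @param write_trials If `TRUE`, also simulate and write trial logs
#'   consistent with each subject's accuracies.
#' @param seed Seed for the trial-log simulation.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir, write_trials = TRUE, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (id in names(cohort$bold)) {
    p <- file.path(dir, paste0(id, "_bold.nii.gz"))
    write_volume(cohort$bold[[id]], p)
    paths <- c(paths, p)
  }
  pm <- file.path(dir, "mask.nii.gz")
  write_volume(cohort$mask, pm)
  pp <- file.path(dir, "phenotypes.csv")
  write.csv(cohort$phenotypes, pp, row.names = FALSE)
  paths <- c(paths, pm, pp)
  if (write_trials) {
    logs <- list()
    for (i in seq_len(nrow(cohort$phenotypes))) {
      row <- cohort$phenotypes[i, ]
      for (cond in c("happy", "fearful")) {
        acc <- if (cond == "happy") row$acc_happy else row$acc_fear
        logs[[length(logs) + 1L]] <- make_trial_log(
          acc, subject_id = row$subject_id, condition = cond,
          seed = stage_seed(seed, paste0("trials_", row$subject_id, cond)))
      }
    }
    pt <- file.path(dir, "trials.csv")
    write.csv(do.call(rbind, logs), pt, row.names = FALSE)
    paths <- c(paths, pt)
  }
  invisible(paths)
}
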