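#' BOLD 4D time-series container
#'
#' Wraps a subject's 4D voxel time-series together with its grid geometry
#' and repetition time (TR).  Data are stored as an `(x, y, z, t)` array of
#' signal intensities.
#'
#' @param data Numeric 4D array `(x, y, z, t)` of finite values.
#' @param voxel_size_mm Numeric length-3, voxel edge lengths in mm.
#' @param tr_s Repetition time in seconds (sampling interval).
#' @return An object of class `bold4d` with elements `data`, `voxel_size_mm`
#'   and `tr_s`.
#' @export
#' @examples
#' b <- bold4d(array(rnorm(8 * 8 * 8 * 10), c(8, 8, 8, 10)),
#'             voxel_size_mm = c(3, 3, 3), tr_s = 2)
#' n_timepoints(b)
bold4d <- function(data, voxel_size_mm, tr_s) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("`data` must be a 4D array (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("a bold4d needs at least 2 timepoints")
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  tr_s <- as.numeric(tr_s)
  if (length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0)
    stop("`tr_s` must be a positive scalar")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, tr_s = tr_s),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold4d> %d x %d x %d voxels, %d timepoints, TR %g s, voxel %s mm\n",
              d[1], d[2], d[3], d[4], x$tr_s,
              paste(signif(x$voxel_size_mm, 3), collapse = " x ")))
  invisible(x)
}

#' Grid dimensions and timepoint count of a bold4d
#' @param bold A [bold4d] object.
#' @return `grid_dims()`: integer length-3; `n_timepoints()`: integer.
#' @export
grid_dims <- function(bold) dim(bold$data)[1:3]

#' @rdname grid_dims
#' @export
n_timepoints <- function(bold) dim(bold$data)[4]

#' Brain mask
#'
#' A logical 3D array of in-brain voxels sharing the grid of the volumes it
#' is applied to.
#'
#' @param mask Logical 3D array (or 0/1 numeric array).
#' @param voxel_size_mm Numeric length-3 voxel size in mm.
#' @return An object of class `brain_mask` with elements `mask` (logical
#'   array), `voxel_size_mm` and `n_voxels`.
#' @export
brain_mask <- function(mask, voxel_size_mm) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a 3D array")
  storage.mode(mask) <- "logical"
  if (anyNA(mask)) stop("`mask` contains NA")
  n_voxels <- sum(mask)
  if (n_voxels < 1L) stop("mask contains no voxels")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 positive reals")
  structure(list(mask = mask, voxel_size_mm = voxel_size_mm,
                 n_voxels = n_voxels),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<brain_mask> %d x %d x %d grid, %d in-mask voxels\n",
              d[1], d[2], d[3], x$n_voxels))
  invisible(x)
}

# Internal: check a volume/bold shares the mask grid.
check_grid <- function(dims, mask, what = "volume") {
  if (!all(dims[1:3] == dim(mask$mask)))
    stop(sprintf("%s grid (%s) does not match mask grid (%s)", what,
                 paste(dims[1:3], collapse = "x"),
                 paste(dim(mask$mask), collapse = "x")))
  invisible(TRUE)
}

# Internal: flatten a bold4d to a voxels x time matrix (all voxels).
bold_matrix <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
}

# Internal: rebuild a bold4d from a voxels x time matrix.
matrix_bold <- function(m, template) {
  d <- dim(template$data)
  template$data <- array(m, dim = c(d[1:3], ncol(m)))
  template
}

# Internal: stack a list of 3D maps (or map objects with $data) into a
# voxels x subjects matrix restricted to the mask.
stack_maps <- function(maps, mask) {
  keep <- mask$mask
  cols <- lapply(maps, function(m) {
    a <- if (is.list(m) && !is.null(m$data)) m$data else m
    if (!is.array(a) || length(dim(a)) != 3L)
      stop("maps must be 3D arrays or map objects")
    check_grid(dim(a), mask, "map")
    a[keep]
  })
  do.call(cbind, cols)
}
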