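#' Define a common volumetric grid
#'
#' All subjects in an analysis share one spatial grid (a fixed matrix size and
#' voxel size). Registration to a common space is assumed to have happened
#' upstream; this package never resamples.
#'
#' @param dims Integer triple `(nx, ny, nz)`, all at least 1.
#' @param voxel_size Numeric triple of voxel edge lengths in mm, all positive.
#' @param affine Optional 4x4 voxel-to-world transform; defaults to a scaled
#'   identity built from `voxel_size`.
#' @return An object of class `volume_grid`.
#' @export
#' @examples
#' volume_grid(c(16, 16, 8), voxel_size = c(3, 3, 3))
volume_grid <- function(dims, voxel_size = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L)) {
    stop("`dims` must be three integers >= 1", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be three positive lengths (mm)", call. = FALSE)
  }
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(
    list(dims = dims, voxel_size = voxel_size, affine = affine),
    class = "volume_grid"
  )
}

#' @export
format.volume_grid <- function(x, ...) {
  sprintf(
    "<volume_grid %dx%dx%d, %.3gx%.3gx%.3g mm>",
    x$dims[1], x$dims[2], x$dims[3],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

grids_equal <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

#' Create a brain mask on a grid
#'
#' The mask fixes which voxels carry data. Throughout the package a "field" is
#' a numeric vector of length `V = sum(inside)` in the fixed voxel storage
#' order (x fastest, then y, then z), so masking and unmasking are mutually
#' inverse on the inside-mask region.
#'
#' @param grid A [volume_grid()].
#' @param inside Logical array (or vector) over the grid; at least one `TRUE`.
#' @return An object of class `brain_mask` with elements `grid`, `inside`
#'   (logical array) and `V` (inside-voxel count).
#' @export
brain_mask <- function(grid, inside) {
  stopifnot(inherits(grid, "volume_grid"))
  inside <- array(as.logical(inside), dim = grid$dims)
  if (any(is.na(inside))) stop("mask contains NA", call. = FALSE)
  V <- sum(inside)
  if (V < 1L) stop("mask must contain at least one voxel", call. = FALSE)
  structure(
    list(grid = grid, inside = inside, V = as.integer(V)),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask %s, V = %d (%.1f%% of grid)>\n",
              format(x$grid), x$V, 100 * x$V / n_voxels(x$grid)))
  invisible(x)
}

#' Convert between masked fields and full 3D volumes
#'
#' @param field Numeric vector of length `mask$V`.
#' @param mask A [brain_mask()].
#' @param fill Value used outside the mask (default 0).
#' @return `field_to_volume()` returns a 3D array on the grid;
#'   `volume_to_field()` extracts the inside-mask values of a 3D array as a
#'   vector of length `mask$V`.
#' @export
field_to_volume <- function(field, mask, fill = 0) {
  stopifnot(inherits(mask, "brain_mask"))
  if (length(field) != mask$V) {
    stop(sprintf("field length %d != mask V %d", length(field), mask$V), call. = FALSE)
  }
  vol <- array(fill, dim = mask$grid$dims)
  vol[mask$inside] <- field
  vol
}

#' @rdname field_to_volume
#' @param volume 3D array on the mask's grid.
#' @export
volume_to_field <- function(volume, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  if (!identical(dim(volume), mask$grid$dims)) {
    stop("volume dimensions do not match the mask grid", call. = FALSE)
  }
  as.numeric(volume[mask$inside])
}

#' Construct a masked BOLD time series
#'
#' @param subject_id Subject identifier.
#' @param mask A [brain_mask()].
#' @param data `T x V` numeric matrix, timepoints by inside-mask voxels.
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(subject_id, mask, data, tr_seconds = 2) {
  stopifnot(inherits(mask, "brain_mask"), is.matrix(data))
  if (ncol(data) != mask$V) {
    stop(sprintf("data has %d columns but mask V = %d", ncol(data), mask$V), call. = FALSE)
  }
  if (nrow(data) < 10L) stop("need at least 10 timepoints", call. = FALSE)
  if (!all(is.finite(data))) stop("non-finite values in BOLD data", call. = FALSE)
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  structure(
    list(
      subject_id = as.character(subject_id),
      grid = mask$grid, mask = mask,
      T = nrow(data), data = data,
      tr_seconds = tr_seconds
    ),
    class = "bold_series"
  )
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series '%s': T = %d, V = %d, TR = %.3g s>\n",
              x$subject_id, x$T, x$mask$V, x$tr_seconds))
  invisible(x)
}

#' Read and write 4D BOLD series as NIfTI
#'
#' `read_bold()` loads a 4D NIfTI file, checks it against the supplied mask's
#' grid, and returns the masked time-by-voxel matrix. `write_bold()` writes a
#' `bold_series` back to disk with zeros outside the mask.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param mask A [brain_mask()] on the file's grid.
#' @param subject_id Identifier attached to the returned series.
#' @param tr_seconds Repetition time; if `NULL`, taken from the NIfTI header.
#' @return A [bold_series()].
#' @export
read_bold <- function(path, mask, subject_id = basename(path), tr_seconds = NULL) {
  stopifnot(inherits(mask, "brain_mask"))
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) stop("expected a 4D volume: ", path, call. = FALSE)
  if (!identical(dim(arr)[1:3], mask$grid$dims)) {
    stop(sprintf("grid mismatch: file is %s, mask grid is %s",
                 paste(dim(arr)[1:3], collapse = "x"),
                 paste(mask$grid$dims, collapse = "x")), call. = FALSE)
  }
  nT <- dim(arr)[4]
  flat <- matrix(arr, nrow = prod(mask$grid$dims), ncol = nT)
  data <- t(flat[as.vector(mask$inside), , drop = FALSE])
  if (!all(is.finite(data))) stop("non-finite values in ", path, call. = FALSE)
  if (is.null(tr_seconds)) {
    pd <- attr(img, "pixdim")
    tr_seconds <- if (!is.null(pd) && length(pd) >= 4 && pd[4] > 0) pd[4] else 2
  }
  bold_series(subject_id, mask, data, tr_seconds = tr_seconds)
}

#' @rdname read_bold
#' @param series A [bold_series()].
#' @export
write_bold <- function(series, path) {
  stopifnot(inherits(series, "bold_series"))
  dims <- series$grid$dims
  arr <- array(0, dim = c(dims, series$T))
  flat <- matrix(arr, nrow = prod(dims), ncol = series$T)
  flat[as.vector(series$mask$inside), ] <- t(series$data)
  arr <- array(flat, dim = c(dims, series$T))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$grid$voxel_size, series$tr_seconds)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read and write 3D statistical maps as NIfTI
#'
#' `write_map()` embeds a masked field into the full grid (zeros outside the
#' mask); `read_map()` extracts the inside-mask field from a 3D file.
#'
#' @param field Numeric vector of length `mask$V`.
#' @param mask A [brain_mask()].
#' @param path Output/input NIfTI path.
#' @return `write_map()` returns `path` invisibly; `read_map()` returns a
#'   numeric field of length `mask$V`.
#' @export
write_map <- function(field, mask, path) {
  vol <- field_to_volume(field, mask)
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- mask$grid$voxel_size
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, mask) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) stop("expected a 3D volume: ", path, call. = FALSE)
  volume_to_field(arr, mask)
}

#' @rdname write_map
#' @export
write_mask <- function(mask, path) {
  vol <- array(0, dim = mask$grid$dims)
  vol[mask$inside] <- 1
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- mask$grid$voxel_size
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_map
#' @param voxel_size Voxel size used when reconstructing the grid.
#' @export
read_brain_mask <- function(path, voxel_size = NULL) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D mask: ", path, call. = FALSE)
  if (is.null(voxel_size)) {
    pd <- attr(img, "pixdim")
    voxel_size <- if (!is.null(pd) && length(pd) >= 3) pd[1:3] else c(3, 3, 3)
  }
  grid <- volume_grid(dim(arr), voxel_size = voxel_size)
  brain_mask(grid, arr != 0)
}
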