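# NIfTI input/output and the multi-resolution pyramid.
#
# Intensities are read as floating point; the voxel-to-world affine comes
# from the sform, falling back to the qform (with a warning) and finally to
# a pixdim-scaled identity.  Volumes whose third dimension is 1 are treated
# as 2D problems with 3x3 homogeneous affines.

affine_3d_to_2d <- function(M4) M4[c(1, 2, 4), c(1, 2, 4)]

affine_2d_to_3d <- function(M3) {
  M4 <- diag(4)
  M4[c(1, 2, 4), c(1, 2, 4)] <- M3
  M4
}

#' Read a NIfTI scan
#'
#' @param path NIfTI-1 file.
#' @param lam noise precision to attach (`NA` to estimate later).
#' @param t acquisition time (years).
#' @return a [scan_image()].
#' @export
read_scan <- function(path, lam = NA_real_, t = NA_real_) {
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  arr <- as.array(img)
  if (hdr$sform_code > 0) {
    M4 <- structure(RNifti::xform(img, useQuaternionFirst = FALSE),
                    code = NULL)
  } else if (hdr$qform_code > 0) {
    warning("no sform in ", path, "; falling back to qform")
    M4 <- structure(RNifti::xform(img, useQuaternionFirst = TRUE),
                    code = NULL)
  } else {
    warning("no sform/qform in ", path, "; using pixdim-scaled identity")
    M4 <- diag(c(hdr$pixdim[2:4], 1))
  }
  M4 <- matrix(as.numeric(M4), 4, 4)
  dims <- dim(arr)
  dims <- dims[dims > 1 | seq_along(dims) <= 2]
  if (length(dims) > 2L && length(dim(arr)) >= 3L && dim(arr)[3] > 1L) {
    arr <- array(as.numeric(arr), dim(arr)[1:3])
    M <- M4
  } else {
    arr <- array(as.numeric(arr), dim(arr)[1:2])
    M <- affine_3d_to_2d(M4)
  }
  scan_image(arr, M, lam = if (is.na(lam)) 1 else lam, t = t)
}

#' Write an array with a voxel-to-world affine as NIfTI
#'
#' 2D grids are embedded as single-slice volumes; multi-component fields
#' (velocities) go into the 4th dimension.
#'
#' @param x numeric array (or M x d matrix with `dims` supplied).
#' @param M voxel-to-world affine ((d+1) x (d+1)).
#' @param path output file.
#' @param dims spatial grid dimensions when `x` is a matrix.
#' @export
write_volume <- function(x, M, path, dims = NULL) {
  if (is.matrix(x) && !is.null(dims)) {
    nc <- ncol(x)
    x <- array(x, c(dims, nc))
  }
  da <- dim(x)
  d <- if (!is.null(dims)) length(dims) else min(length(da), 3L)
  if (nrow(M) == 3L) M4 <- affine_2d_to_3d(M) else M4 <- M
  if (d == 2L) {
    spatial <- da[1:2]
    rest <- if (length(da) > 2L) da[-(1:2)] else integer(0)
    x <- array(x, c(spatial, 1L, rest))
  }
  img <- RNifti::asNifti(x)
  img <- RNifti::`sform<-`(img, structure(M4, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- multi-resolution pyramid ----------------------------------------------

smooth_121 <- function(A) {
  dims <- dim(A)
  for (k in seq_along(dims)) {
    if (dims[k] < 3L) next
    A <- (shift_axis(A, k, -1L) + 2 * A + shift_axis(A, k, 1L)) / 4
  }
  A
}

#' Restrict an image to the next coarser level
#'
#' Smooths with a separable 1-2-1 kernel and keeps every second sample, so
#' coarse voxel c sits at fine voxel 2c.
#'
#' @param A numeric array.
#' @return coarser array of dimensions `ceiling(dim(A) / 2)`.
#' @export
restrict_image <- function(A) {
  A <- smooth_121(A)
  idx <- lapply(dim(A), function(n) seq(1L, n, by = 2L))
  do.call(`[`, c(list(A), idx, list(drop = FALSE)))
}

#' Prolong a velocity field to a finer level
#'
#' Linear interpolation at the fine-grid positions with values rescaled to
#' fine voxel units.
#'
#' @param v matrix `prod(coarse_dims)` x d.
#' @param coarse_dims,fine_dims grid dimensions.
#' @export
prolong_velocity <- function(v, coarse_dims, fine_dims) {
  P <- grid_coords(fine_dims) / 2
  2 * sample_field_wrap(v, coarse_dims, P, degree = 1L)
}

#' Prolong a scalar field (log-bias) to a finer level
#'
#' @param b vector over the coarse grid.
#' @param coarse_dims,fine_dims grid dimensions.
#' @export
prolong_scalar <- function(b, coarse_dims, fine_dims) {
  S <- spline_rep(array(b, coarse_dims), 1L, "reflect")
  spline_eval(S, grid_coords(fine_dims) / 2)$values
}

pyramid_levels <- function(A, levels) {
  out <- vector("list", levels)
  out[[1]] <- A
  for (l in seq_len(levels - 1L)) {
    if (any(dim(out[[l]]) < 8L)) {
      stop("grid too small for ", levels, " pyramid levels")
    }
    out[[l + 1L]] <- restrict_image(out[[l]])
  }
  out
}

#' Multi-resolution pyramid of a set of images
#'
#' @param images list of arrays on a common grid.
#' @param levels number of levels (1 = finest only).
#' @return list over levels (finest first), each a list of images.
#' @export
build_pyramid <- function(images, levels) {
  stopifnot(levels >= 1L)
  per_image <- lapply(images, pyramid_levels, levels = levels)
  lapply(seq_len(levels), function(l) lapply(per_image, `[[`, l))
}
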