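#' Image grid descriptor
#'
#' A lightweight description of a 3D voxel grid: its dimensions, the 4x4
#' voxel-to-world (NIfTI) affine in millimetres, and the voxel volume in mm^3
#' derived from the affine. All images, masks and atlases in a pipeline run
#' must share one grid; [same_grid()] enforces this.
#'
#' @param shape Integer vector of length 3, voxel counts along each axis.
#' @param affine 4x4 numeric voxel-to-world matrix (mm). Defaults to a
#'   diagonal affine built from `spacing`, centred at the origin.
#' @param spacing Voxel edge length(s) in mm, length 1 or 3. Used only when
#'   `affine` is not given. Defaults to 1.5 mm isotropic, the resampled
#'   resolution conventional for VBM gray-matter maps.
#'
#' @return An object of class `image_grid` with fields `shape`, `affine`,
#'   `voxel_volume` (mm^3).
#' @examples
#' g <- image_grid(c(16, 16, 16))
#' g$voxel_volume  # 3.375 mm^3
#' @export
image_grid <- function(shape, affine = NULL, spacing = 1.5) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    abort("`shape` must be 3 positive integers.")
  }
  if (is.null(affine)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    affine <- diag(c(spacing, 1))
    # centre the FOV on the world origin so left/right hemispheres split at x = 0
    affine[1:3, 4] <- -spacing * (shape - 1L) / 2
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.numeric(affine)) {
    abort("`affine` must be a numeric 4x4 matrix.")
  }
  dt <- det(affine[1:3, 1:3])
  if (!is.finite(dt) || abs(dt) < .Machine$double.eps) {
    abort("`affine` rotation/zoom block is singular.")
  }
  structure(
    list(shape = shape, affine = affine, voxel_volume = abs(dt)),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(
    "<image_grid> ", paste(x$shape, collapse = " x "),
    " voxels, voxel volume ", format(x$voxel_volume, digits = 4), " mm^3\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ", format(x$voxel_volume, digits = 4), " mm^3")
}

# max |elementwise| affine tolerance: header jitter below physical meaning
AFFINE_TOL <- 1e-4

#' Test two grids for compatibility
#'
#' Grids are compatible when shapes match exactly and affines agree to within
#' 1e-4 mm elementwise.
#'
#' @param a,b `image_grid` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) <= AFFINE_TOL
}

stop_if_grid_mismatch <- function(a, b, what = "image") {
  if (!same_grid(a, b)) {
    abort(paste0("Grid mismatch: ", what, " is not on the analysis grid."))
  }
  invisible(TRUE)
}

#' World coordinates of voxel indices
#'
#' Voxel indices are 0-based (NIfTI convention); world coordinates come from
#' the affine.
#'
#' @param grid An `image_grid`.
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world (mm) coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  h <- cbind(ijk, 1)
  xyz <- h %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

# linear index (1-based, column-major) <-> 0-based ijk
index_to_ijk <- function(grid, idx) {
  arrayInd(idx, grid$shape) - 1L
}

ijk_to_index <- function(grid, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3L)
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}
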