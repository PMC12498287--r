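#' Read a 3D NIfTI image and its grid
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (3D numeric array) and `grid` (an [image_grid()]).
#' @export
read_image <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  if (length(dim(arr)) != 3L) {
    abort(paste0("Expected a 3D image: ", path))
  }
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = dim(aff))
  list(data = arr, grid = image_grid(dim(arr), affine = aff))
}

#' Write a 3D array as NIfTI on a given grid
#'
#' @param data 3D numeric, logical, or integer array.
#' @param grid An [image_grid()] supplying the affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image <- function(data, grid, path) {
  if (!all(dim(data) == grid$shape)) {
    abort("`data` dimensions do not match `grid$shape`.")
  }
  storage.mode(data) <- if (is.logical(data)) "integer" else storage.mode(data)
  im <- RNifti::asNifti(data)
  im <- RNifti::`sform<-`(im, structure(grid$affine, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Gray-matter-volume stack
#'
#' Bundles per-subject GMV images on a shared grid into a subjects-by-voxels
#' matrix plus an analysis mask. Voxels are stored in column-major array
#' order; `mask` is a logical vector over all grid voxels.
#'
#' @param data Subjects x voxels numeric matrix (rows follow `subject_id`).
#' @param grid An [image_grid()].
#' @param mask Logical vector, one element per voxel; defaults to voxels with
#'   nonzero variance across subjects and finite values for every subject.
#' @param subject_id Character vector of subject identifiers, one per row.
#' @return An object of class `gmv_stack`.
#' @export
gmv_stack <- function(data, grid, mask = NULL, subject_id = NULL) {
  data <- as.matrix(data)
  nv <- prod(grid$shape)
  if (ncol(data) != nv) {
    abort("`data` must have one column per grid voxel.")
  }
  if (is.null(subject_id)) subject_id <- paste0("sub", seq_len(nrow(data)))
  if (length(subject_id) != nrow(data) || anyDuplicated(subject_id)) {
    abort("`subject_id` must be unique, one per row of `data`.")
  }
  if (is.null(mask)) {
    finite <- colSums(!is.finite(data)) == 0L
    v <- rep(0, nv)
    v[finite] <- matrixStats_colVars(data[, finite, drop = FALSE])
    mask <- finite & v > 0
  }
  mask <- as.logical(mask)
  if (length(mask) != nv) abort("`mask` length must equal the voxel count.")
  bad <- mask & (colSums(!is.finite(data)) > 0L)
  if (any(bad)) abort("Mask includes voxels with non-finite data.")
  structure(
    list(data = data, grid = grid, mask = mask, subject_id = subject_id),
    class = "gmv_stack"
  )
}

# column variances without a matrixStats dependency
matrixStats_colVars <- function(m) {
  if (ncol(m) == 0L) return(numeric(0))
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' @export
print.gmv_stack <- function(x, ...) {
  cat(
    "<gmv_stack> ", nrow(x$data), " subjects on ", format(x$grid),
    "; mask ", sum(x$mask), "/", length(x$mask), " voxels\n",
    sep = ""
  )
  invisible(x)
}

#' Read per-subject GMV images into a stack
#'
#' All images must share the grid of the first (shape exactly; affine to
#' within 1e-4 mm elementwise). Subject order follows `image_paths`.
#'
#' @param image_paths Character vector of NIfTI paths, one per subject.
#' @param mask_path Optional NIfTI mask path (nonzero = in mask).
#' @param subject_id Optional subject identifiers; default is the file stem.
#' @return A [gmv_stack()].
#' @export
read_gmv_stack <- function(image_paths, mask_path = NULL, subject_id = NULL) {
  if (length(image_paths) < 1L) abort("Need at least one image.")
  first <- read_image(image_paths[[1]])
  grid <- first$grid
  nv <- prod(grid$shape)
  data <- matrix(NA_real_, length(image_paths), nv)
  data[1, ] <- as.vector(first$data)
  for (i in seq_along(image_paths)[-1]) {
    im <- read_image(image_paths[[i]])
    if (!same_grid(grid, im$grid)) {
      abort(paste0("Grid-incompatible image: ", image_paths[[i]]))
    }
    data[i, ] <- as.vector(im$data)
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_image(mask_path)
    stop_if_grid_mismatch(grid, m$grid, "mask")
    mask <- as.vector(m$data) != 0
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(image_paths))
  }
  gmv_stack(data, grid, mask = mask, subject_id = subject_id)
}

#' Write a GMV stack as one NIfTI per subject
#'
#' @param stack A [gmv_stack()].
#' @param dir Output directory (created if absent).
#' @return Tibble with `subject_id` and `path`.
#' @export
write_gmv_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stack$subject_id, ".nii.gz"))
  for (i in seq_along(paths)) {
    write_image(array(stack$data[i, ], stack$grid$shape), stack$grid, paths[i])
  }
  tibble(subject_id = stack$subject_id, path = paths)
}

#' Read an integer-labelled atlas image
#'
#' @param path NIfTI path; voxel values must be (near-)integer labels, 0 =
#'   background.
#' @param grid Optional reference [image_grid()] the atlas must match.
#' @param region_names Optional named character vector mapping label ids
#'   (names, coercible to integer) to region names.
#' @return List of class `atlas_image` with `labels` (integer 3D array),
#'   `grid`, and `regions`, a tibble of `region_id`, `region_name`,
#'   `size_voxels`.
#' @export
read_atlas <- function(path, grid = NULL, region_names = NULL) {
  im <- read_image(path)
  if (!is.null(grid)) stop_if_grid_mismatch(grid, im$grid, "atlas")
  atlas_image(im$data, im$grid, region_names)
}

#' Construct an atlas object from a labelled array
#'
#' @param labels 3D array of integer region labels (0 = background).
#' @param grid The [image_grid()] the labels live on.
#' @param region_names Optional named character vector (names = label ids).
#' @return An `atlas_image` object; see [read_atlas()].
#' @export
atlas_image <- function(labels, grid, region_names = NULL) {
  v <- as.vector(labels)
  if (any(abs(v - round(v)) > 1e-6)) {
    abort("Atlas image has non-integer labels.")
  }
  labels <- array(as.integer(round(v)), grid$shape)
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0L]
  sizes <- if (length(ids)) tabulate(factor(as.vector(labels), levels = ids)) else integer(0)
  nm <- as.character(ids)
  if (!is.null(region_names)) {
    hit <- match(nm, names(region_names))
    nm <- ifelse(is.na(hit), paste0("region_", nm), unname(region_names[hit]))
  } else {
    nm <- paste0("region_", nm)
  }
  structure(
    list(
      labels = labels, grid = grid,
      regions = tibble(region_id = ids, region_name = nm, size_voxels = sizes)
    ),
    class = "atlas_image"
  )
}

#' @export
print.atlas_image <- function(x, ...) {
  cat("<atlas_image> ", nrow(x$regions), " regions on ", format(x$grid), "\n", sep = "")
  invisible(x)
}
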