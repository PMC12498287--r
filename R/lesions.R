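#' Per-patient lesion mask set
#'
#' @param masks Named list (by patient id) of logical vectors or 3D logical
#'   arrays on the analysis grid.
#' @param grid The shared [image_grid()].
#' @param allow_empty Permit all-`FALSE` masks (default `FALSE`: an empty
#'   lesion in a lesion study is almost always an upstream error).
#' @return Object of class `lesion_mask_set` with `masks` (list of logical
#'   vectors) and `grid`.
#' @export
lesion_mask_set <- function(masks, grid, allow_empty = FALSE) {
  nv <- prod(grid$shape)
  masks <- lapply(masks, function(m) {
    v <- as.logical(as.vector(m))
    if (length(v) != nv) abort("Lesion mask is not on the analysis grid.")
    if (anyNA(v)) abort("Lesion masks must not contain NA.")
    v
  })
  if (!allow_empty && length(masks) && any(!vapply(masks, any, logical(1)))) {
    abort("Empty lesion mask (set `allow_empty = TRUE` to permit).")
  }
  structure(list(masks = masks, grid = grid), class = "lesion_mask_set")
}

#' Read lesion masks from NIfTI files
#'
#' @param paths Named character vector (or list) of mask paths; names become
#'   patient ids (default: file stems).
#' @param grid Reference [image_grid()] every mask must match.
#' @inheritParams lesion_mask_set
#' @return A [lesion_mask_set()].
#' @export
read_lesion_masks <- function(paths, grid, allow_empty = FALSE) {
  paths <- unlist(paths)
  if (is.null(names(paths))) {
    names(paths) <- sub("\\.nii(\\.gz)?$", "", basename(paths))
  }
  masks <- lapply(paths, function(p) {
    im <- read_image(p)
    stop_if_grid_mismatch(grid, im$grid, basename(p))
    as.vector(im$data) != 0
  })
  lesion_mask_set(masks, grid, allow_empty = allow_empty)
}

#' Group lesion probability map
#'
#' Voxelwise fraction of patients whose lesion covers the voxel: the sum of
#' all binary lesion masks divided by the number of patients.
#'
#' @param lesions A [lesion_mask_set()] with at least one mask.
#' @return Object of class `lesion_prob_map`: list with `prob` (numeric 3D
#'   array in \[0, 1\]), `n_patients`, `grid`.
#' @export
lesion_probability_map <- function(lesions) {
  if (!length(lesions$masks)) abort("Need at least one lesion mask.")
  counts <- Reduce(`+`, lapply(lesions$masks, as.integer))
  structure(
    list(
      prob = array(counts / length(lesions$masks), lesions$grid$shape),
      n_patients = length(lesions$masks), grid = lesions$grid
    ),
    class = "lesion_prob_map"
  )
}

#' @export
print.lesion_prob_map <- function(x, ...) {
  cat(
    "<lesion_prob_map> ", x$n_patients, " patients; max probability ",
    format(max(x$prob), digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Lesion-exclusion analysis mask
#'
#' Removes from the analysis mask every voxel falling inside the lesion of
#' any patient, so each voxelwise test uses the same subjects and degrees of
#' freedom.
#'
#' @param analysis_mask Logical vector or 3D array on the grid.
#' @param lesions A [lesion_mask_set()].
#' @return Logical vector (voxel order) — `analysis_mask AND NOT
#'   union(lesions)`. Warns if the result is empty.
#' @export
lesion_exclusion_mask <- function(analysis_mask, lesions) {
  nv <- prod(lesions$grid$shape)
  am <- as.logical(as.vector(analysis_mask))
  if (length(am) != nv) abort("Analysis mask is not on the lesion grid.")
  if (length(lesions$masks)) {
    u <- Reduce(`|`, lesions$masks)
    am <- am & !u
  }
  if (!any(am)) warn("Lesion exclusion leaves an empty analysis mask.")
  am
}

#' Per-patient lesion volume report
#'
#' @param lesions A [lesion_mask_set()].
#' @return Tibble with `subject_id`, `n_voxels`, `volume_mm3`, `volume_ml`.
#' @export
lesion_volumes <- function(lesions) {
  n <- vapply(lesions$masks, sum, integer(1))
  tibble(
    subject_id = names(lesions$masks) %||% paste0("patient", seq_along(n)),
    n_voxels = unname(n),
    volume_mm3 = unname(n) * lesions$grid$voxel_volume,
    volume_ml = unname(n) * lesions$grid$voxel_volume / 1000
  )
}
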