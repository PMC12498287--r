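#' Tidy a voxelwise SCN fit
#'
#' One row per in-mask voxel with 0-based voxel indices, the group-specific
#' covariance slopes, the slope-difference estimate, and its t statistic.
#'
#' @param x An `scn_fit`.
#' @param ... Unused.
#' @return A tibble with columns `voxel`, `i`, `j`, `k`, `beta_cs`,
#'   `beta_nc`, `estimate`, `sigma2`, `t`, `p_greater`, `p_two_sided`.
#' @method tidy scn_fit
#' @export
tidy.scn_fit <- function(x, ...) {
  vox <- which(x$mask)
  ijk <- index_to_ijk(x$grid, vox)
  est <- drop(crossprod(x$contrast, x$beta))
  tibble(
    voxel = vox, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    beta_cs = x$beta["seedvol_cs", ], beta_nc = x$beta["seedvol_nc", ],
    estimate = est, sigma2 = x$sigma2, t = x$t,
    p_greater = pt(x$t, x$df, lower.tail = FALSE),
    p_two_sided = 2 * pt(-abs(x$t), x$df)
  )
}

#' One-row summary of a voxelwise SCN fit
#'
#' @param x An `scn_fit`.
#' @param ... Unused.
#' @return A tibble with `seed`, `n_subjects`, `n_voxels`, `df`,
#'   `max_t`, `min_t`, `n_undefined` (voxels with NaN t).
#' @method glance scn_fit
#' @export
glance.scn_fit <- function(x, ...) {
  finite <- is.finite(x$t)
  tibble(
    seed = x$design$seed_name,
    n_subjects = nrow(x$design$X),
    n_voxels = sum(x$mask),
    df = x$df,
    max_t = if (any(finite)) max(x$t[finite]) else NA_real_,
    min_t = if (any(finite)) min(x$t[finite]) else NA_real_,
    n_undefined = sum(!finite)
  )
}
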