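connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    abort("`connectivity` must be 6, 18, or 26.")
  }
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
    "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g))
  )
  as.matrix(g[keep, ])
}

#' Label connected components of a 3D mask
#'
#' Union-find over the masked voxels; labels are independent of voxel
#' visitation order (components are renumbered by their smallest linear
#' voxel index).
#'
#' @param mask Logical 3D array, or logical vector with `dims` given.
#' @param connectivity 6 (faces), 18 (faces + edges, the SPM convention),
#'   or 26 (full neighbourhood).
#' @param dims Grid dimensions when `mask` is a bare vector.
#' @return List with `labels` (integer vector over voxels, 0 = background),
#'   `n` (number of components), `sizes` (integer vector of extents).
#' @export
label_components <- function(mask, connectivity = 18, dims = dim(mask)) {
  if (is.null(dims) || length(dims) != 3L) abort("Need 3D dimensions.")
  off <- connectivity_offsets(as.integer(connectivity))
  m <- as.logical(as.vector(mask))
  nv <- prod(dims)
  labels <- integer(nv)
  idx <- which(m)
  if (!length(idx)) return(list(labels = labels, n = 0L, sizes = integer(0)))

  ijk <- arrayInd(idx, dims)
  pos <- integer(nv)          # voxel linear index -> rank in `idx`
  pos[idx] <- seq_along(idx)
  parent <- seq_along(idx)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(off))) {
    nb <- cbind(ijk[, 1] + off[r, 1], ijk[, 2] + off[r, 2], ijk[, 3] + off[r, 3])
    ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
      nb[, 2] >= 1L & nb[, 2] <= dims[2] &
      nb[, 3] >= 1L & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 1]) + dims[1] * (nb[ok, 2] - 1L) + dims[1] * dims[2] * (nb[ok, 3] - 1L)
    nb_pos <- pos[nb_lin]
    src <- which(ok)[nb_pos > 0L]
    dst <- nb_pos[nb_pos > 0L]
    for (e in seq_along(src)) {
      a <- find(src[e])
      b <- find(dst[e])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  root <- vapply(seq_along(idx), find, integer(1))
  comp <- as.integer(factor(root, levels = sort(unique(root))))
  labels[idx] <- comp
  sizes <- tabulate(comp)
  list(labels = labels, n = length(sizes), sizes = sizes)
}

# largest component size of a logical vector on dims (0 if empty)
max_cluster_extent <- function(supra, dims, connectivity) {
  if (!any(supra)) return(0L)
  lab <- label_components(supra, connectivity, dims = dims)
  max(lab$sizes)
}

#' Threshold a t-map and form clusters
#'
#' Applies the cluster-forming voxel threshold (p < 0.001 by convention) to
#' the contrast t-map and labels suprathreshold voxels into connected
#' components. Voxels with undefined t (NaN) never enter clusters.
#'
#' @param fit An `scn_fit` (or a list with `t`, `df`, `mask`, `grid`).
#' @param p_voxel Voxel-wise cluster-forming p threshold (default 0.001).
#' @param connectivity Cluster connectivity: 6, 18 (default), or 26.
#' @param direction `"greater"` (CS > NC, default), `"less"`, or
#'   `"two.sided"`.
#' @return Tibble of class `scn_clusters`: `cluster_id`, `extent`
#'   (voxels), `peak_t`, `peak_i`, `peak_j`, `peak_k` (0-based voxel
#'   indices). Carries the label image and thresholds as attributes
#'   (`cluster_label_image()`, `attr(, "t_crit")`).
#' @export
threshold_and_label <- function(fit, p_voxel = 0.001, connectivity = 18,
                                direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  dims <- fit$grid$shape
  t_crit <- voxel_t_crit(p_voxel, fit$df, direction)
  stat <- directional_stat(fit$t, direction)
  full <- rep(NA_real_, prod(dims))
  full[fit$mask] <- stat
  supra <- !is.na(full) & full >= t_crit
  lab <- label_components(supra, connectivity, dims = dims)
  tab <- cluster_table_from_labels(lab, full, dims)
  new_scn_clusters(
    tab,
    labels = lab$labels, grid = fit$grid, t_crit = t_crit,
    p_voxel = p_voxel, connectivity = connectivity, direction = direction,
    df = fit$df
  )
}

voxel_t_crit <- function(p_voxel, df, direction) {
  if (p_voxel <= 0 || p_voxel >= 1) abort("`p_voxel` must be in (0, 1).")
  if (direction == "two.sided") qt(1 - p_voxel / 2, df) else qt(1 - p_voxel, df)
}

directional_stat <- function(t, direction) {
  switch(direction, greater = t, less = -t, two.sided = abs(t))
}

cluster_table_from_labels <- function(lab, stat_full, dims) {
  if (lab$n == 0L) {
    return(tibble(
      cluster_id = integer(0), extent = integer(0), peak_t = numeric(0),
      peak_i = integer(0), peak_j = integer(0), peak_k = integer(0)
    ))
  }
  rows <- lapply(seq_len(lab$n), function(cl) {
    vox <- which(lab$labels == cl)
    pk <- vox[which.max(stat_full[vox])]
    ijk <- arrayInd(pk, dims) - 1L
    tibble(
      cluster_id = cl, extent = length(vox), peak_t = stat_full[pk],
      peak_i = ijk[1], peak_j = ijk[2], peak_k = ijk[3]
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$extent))
}

new_scn_clusters <- function(tab, ...) {
  extra <- list(...)
  for (nm in names(extra)) attr(tab, nm) <- extra[[nm]]
  class(tab) <- c("scn_clusters", class(tab))
  tab
}

#' Cluster label image of a cluster table
#'
#' @param clusters An `scn_clusters` tibble.
#' @return Integer 3D array (0 = background).
#' @export
cluster_label_image <- function(clusters) {
  array(attr(clusters, "labels"), attr(clusters, "grid")$shape)
}

#' Cluster-extent FWE by Freedman-Lane permutation
#'
#' Nonparametric family-wise-error control for cluster extent, replacing
#' parametric random-field correction. The GMV data are residualized
#' against the reduced model (group means + confounders, i.e. the design
#' without the two seed-slope columns); residual rows are permuted, added
#' back to the reduced fit, the full model is refit, and the maximum
#' suprathreshold cluster extent is recorded. Each observed cluster gets
#' `p_fwe = (1 + #\{permuted max >= extent\}) / (B + 1)`, so p can never
#' be exactly zero and the smallest attainable value is `1/(B+1)`.
#'
#' @inheritParams fit_scn
#' @inheritParams threshold_and_label
#' @param B Number of permutations (>= 100; default 1000).
#' @param seed RNG seed for the permutation draw.
#' @param alpha FWE level used only to warn when `1/(B+1) > alpha` and to
#'   set the `significant` flag (default 0.05).
#' @return An `scn_clusters` tibble with `p_fwe` and `significant` columns;
#'   the permutation null max-extent distribution is in
#'   `attr(, "null_max_extent")`.
#' @export
cluster_fwe_permutation <- function(stack, design, mask = NULL,
                                    p_voxel = 0.001, connectivity = 18,
                                    direction = c("greater", "less", "two.sided"),
                                    B = 1000, seed = 1, alpha = 0.05) {
  direction <- match.arg(direction)
  if (B < 100) abort("Need at least 100 permutations.")
  if (1 / (B + 1) > alpha) {
    warn(paste0("B = ", B, " cannot reach p_fwe <= ", alpha, "."))
  }
  fit <- fit_scn(stack, design, mask = mask)
  obs <- threshold_and_label(fit, p_voxel, connectivity, direction)

  X <- design$X
  n <- nrow(X)
  df <- fit$df
  dims <- stack$grid$shape
  t_crit <- attr(obs, "t_crit")
  Y <- stack$data[, fit$mask, drop = FALSE]

  # reduced model: the full model constrained to the null hypothesis of the
  # contrast (c'beta = 0, i.e. a common covariance slope in both groups).
  # Residualizing against this keeps group means, confounders AND the shared
  # seed-volume association out of the permuted residuals, so only the
  # group difference in covariance is exchanged.
  cvec <- design$contrast / sqrt(sum(design$contrast^2))
  Nmat <- qr.Q(qr(cbind(cvec)), complete = TRUE)[, -1, drop = FALSE]
  Xr <- X %*% Nmat
  qr_r <- qr(Xr)
  fitted_r <- qr.fitted(qr_r, Y)
  resid_r <- Y - fitted_r

  # full-model pieces reused across permutations
  qr_f <- qr(X)
  Q1 <- qr.Q(qr_f)
  p <- ncol(X)
  XtXinv <- matrix(0, p, p)
  XtXinv[qr_f$pivot, qr_f$pivot] <- chol2inv(qr.R(qr_f))
  cvar <- drop(t(design$contrast) %*% XtXinv %*% design$contrast)
  a_vec <- drop(X %*% XtXinv %*% design$contrast)  # c'beta_hat = a'Y

  supra_full <- rep(FALSE, prod(dims))
  set.seed(seed)
  null_max <- integer(B)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    Ystar <- fitted_r + resid_r[perm, , drop = FALSE]
    qty <- crossprod(Q1, Ystar)
    rss <- colSums(Ystar^2) - colSums(qty^2)
    sigma2 <- pmax(rss, 0) / df
    est <- drop(crossprod(a_vec, Ystar))
    tstar <- rep(NaN, ncol(Ystar))
    ok <- sigma2 > 1e-14 * pmax(colMeans(Ystar^2), .Machine$double.xmin)
    tstar[ok] <- est[ok] / sqrt(sigma2[ok] * cvar)
    stat <- directional_stat(tstar, direction)
    supra_full[] <- FALSE
    supra_full[fit$mask] <- !is.na(stat) & stat >= t_crit
    null_max[b] <- max_cluster_extent(supra_full, dims, connectivity)
  }

  p_fwe <- vapply(
    obs$extent,
    function(k) (1 + sum(null_max >= k)) / (B + 1),
    numeric(1)
  )
  out <- dplyr::mutate(
    as_tibble(obs),
    p_fwe = p_fwe, significant = p_fwe < alpha
  )
  new_scn_clusters(
    out,
    labels = attr(obs, "labels"), grid = stack$grid,
    t_crit = t_crit, p_voxel = p_voxel, connectivity = connectivity,
    direction = direction, df = df, B = B, alpha = alpha,
    null_max_extent = null_max, fit = fit
  )
}
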