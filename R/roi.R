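#' Binary mask of FWE-significant clusters
#'
#' Keeps the voxels of every cluster whose extent-level FWE p-value falls
#' below `alpha_fwe` — step 1 of the ROI-extraction chain.
#'
#' @param clusters An `scn_clusters` tibble carrying `p_fwe` (from
#'   [cluster_fwe_permutation()]).
#' @param alpha_fwe Cluster-level FWE threshold (default 0.05).
#' @return Logical vector over grid voxels.
#' @export
binarize_significant <- function(clusters, alpha_fwe = 0.05) {
  if (!"p_fwe" %in% names(clusters)) {
    abort("Clusters carry no p_fwe; run cluster_fwe_permutation() first.")
  }
  labels <- attr(clusters, "labels")
  keep <- clusters$cluster_id[clusters$p_fwe < alpha_fwe]
  labels %in% keep & labels > 0L
}

#' Union of binary masks
#'
#' Voxelwise logical OR over the per-seed significance masks — step 2 of
#' the ROI-extraction chain.
#'
#' @param masks Non-empty list of logical vectors/arrays of equal length.
#' @return Logical vector.
#' @export
union_mask <- function(masks) {
  if (!length(masks)) abort("Need at least one mask to union.")
  v <- lapply(masks, function(m) as.logical(as.vector(m)))
  len <- lengths(v)
  if (length(unique(len)) != 1L) abort("Masks differ in length (grid mismatch).")
  Reduce(`|`, v)
}

#' Select atlas regions by overlap with a union mask
#'
#' For every atlas region, computes the ratio of (region intersect union)
#' voxels to the region's own size; a region is selected when the ratio
#' strictly exceeds the threshold (ratio exactly at threshold is NOT
#' selected) — steps 3-4 of the ROI-extraction chain.
#'
#' @param union Logical vector/array on the atlas grid.
#' @param atlas An `atlas_image`.
#' @param threshold Overlap-ratio cutoff (default 0.10).
#' @return Tibble (one row per atlas region): `region_id`, `region_name`,
#'   `size_voxels`, `intersect_voxels`, `overlap_ratio`, `selected`.
#' @export
select_rois <- function(union, atlas, threshold = 0.10) {
  if (!nrow(atlas$regions)) abort("Atlas has no regions.")
  u <- as.logical(as.vector(union))
  lab <- as.vector(atlas$labels)
  if (length(u) != length(lab)) abort("Union mask is not on the atlas grid.")
  ids <- atlas$regions$region_id
  inter <- tabulate(factor(lab[u & lab > 0L], levels = ids), nbins = length(ids))
  out <- dplyr::mutate(
    atlas$regions,
    intersect_voxels = inter,
    overlap_ratio = inter / .data$size_voxels,
    selected = .data$overlap_ratio > threshold
  )
  out
}

#' Build ROI voxel masks from an overlap report
#'
#' @param report Output of [select_rois()].
#' @param atlas The `atlas_image` the report refers to.
#' @param selected_only Keep only selected regions (default `TRUE`).
#' @return Named list of logical voxel vectors (names = region names).
#' @export
roi_masks <- function(report, atlas, selected_only = TRUE) {
  rows <- if (selected_only) dplyr::filter(report, .data$selected) else report
  lab <- as.vector(atlas$labels)
  out <- lapply(rows$region_id, function(id) lab == id)
  names(out) <- rows$region_name
  out
}

#' Per-subject mean GMV within each ROI
#'
#' Arithmetic mean of in-mask ROI voxels per subject — step 5 of the
#' ROI-extraction chain. ROIs are intersected with the analysis mask first
#' (so lesion-excluded voxels never enter a mean); an ROI emptied by the
#' mask is dropped with a warning.
#'
#' @param stack A [gmv_stack()].
#' @param rois Named list of logical voxel vectors (e.g. [roi_masks()]).
#' @param mask Optional analysis mask (e.g. [lesion_exclusion_mask()]);
#'   defaults to the stack's own mask.
#' @return Tibble: `subject_id` plus one mean-GMV column per surviving ROI.
#' @export
extract_mean_gmv <- function(stack, rois, mask = NULL) {
  if (!length(rois)) abort("Need at least one ROI.")
  m <- stack$mask
  if (!is.null(mask)) m <- m & as.logical(as.vector(mask))
  cols <- list()
  for (nm in names(rois)) {
    vox <- which(as.logical(as.vector(rois[[nm]])) & m)
    if (!length(vox)) {
      warn(paste0("ROI '", nm, "' is empty after masking; dropped."))
      next
    }
    cols[[nm]] <- rowMeans(stack$data[, vox, drop = FALSE])
  }
  if (!length(cols)) abort("All ROIs were emptied by the analysis mask.")
  dplyr::bind_cols(tibble(subject_id = stack$subject_id), as_tibble(cols))
}

#' Post-hoc ROI-level covariance GLM
#'
#' Refits the seed-covariance model with each ROI's mean GMV as the
#' response and tests the slope-difference contrast, Bonferroni-adjusted
#' over the full family of (seed, ROI) tests actually performed.
#'
#' @param cohort Validated cohort tibble.
#' @param roi_means Tibble from [extract_mean_gmv()] (subject order must
#'   match the cohort).
#' @param seeds Named list of seed-volume vectors aligned to cohort rows
#'   (names label the seeds), or a single numeric vector.
#' @param zscore_scope Passed to [build_scn_design()].
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @return Tibble: `seed`, `roi`, `estimate` (slope difference), `t`,
#'   `df`, `p_value` (two-sided), `p_bonf`, `significant`.
#' @export
posthoc_roi_glm <- function(cohort, roi_means, seeds,
                            zscore_scope = "pooled", alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  if (!identical(cohort$subject_id, roi_means$subject_id)) {
    abort("`roi_means` subject order must match the cohort.")
  }
  if (is.numeric(seeds)) seeds <- list(seed = seeds)
  roi_names <- setdiff(names(roi_means), "subject_id")
  if (!length(roi_names)) abort("`roi_means` has no ROI columns.")
  rows <- list()
  for (sd_nm in names(seeds)) {
    design <- build_scn_design(
      cohort, seeds[[sd_nm]],
      zscore_scope = zscore_scope, seed_name = sd_nm
    )
    df <- nrow(design$X) - ncol(design$X)
    qr_f <- qr(design$X)
    Y <- as.matrix(roi_means[, roi_names, drop = FALSE])
    fit <- glm_contrast(design$X, Y, design$contrast, df, qr_X = qr_f)
    rows[[sd_nm]] <- tibble(
      seed = sd_nm, roi = roi_names,
      estimate = fit$estimate, t = fit$t, df = df,
      p_value = 2 * pt(-abs(fit$t), df)
    )
  }
  out <- dplyr::bind_rows(rows)
  out$p_bonf <- bonferroni(out$p_value, family_size = nrow(out))
  out$significant <- !is.na(out$p_bonf) & out$p_bonf < alpha
  out
}
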