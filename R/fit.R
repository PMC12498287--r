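#' Fit the seed-covariance GLM at every voxel
#'
#' Ordinary least squares of the design against GMV at each in-mask voxel,
#' with the slope-difference contrast tested by
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` on `n - p` degrees of freedom.
#' Voxels whose residual variance is numerically zero (e.g. constant GMV
#' across subjects, or a noise-free fixture fitted exactly) get `t = NaN`
#' and are excluded from thresholding downstream.
#'
#' @param stack A [gmv_stack()].
#' @param design An [build_scn_design()] result aligned to the stack's
#'   subject order.
#' @param mask Optional logical analysis mask (e.g. from
#'   [lesion_exclusion_mask()]); intersected with the stack's own mask.
#' @return Object of class `scn_fit`: `beta` (p x V coefficients over
#'   in-mask voxels), `sigma2`, `t` (contrast t-map, in-mask), `df`,
#'   `contrast`, `mask` (logical over all grid voxels), `grid`, `design`.
#' @export
fit_scn <- function(stack, design, mask = NULL) {
  stopifnot(inherits(stack, "gmv_stack"), inherits(design, "scn_design"))
  X <- design$X
  n <- nrow(X)
  if (n != nrow(stack$data)) abort("Design and stack disagree on subjects.")
  if (!identical(design$cohort$subject_id, stack$subject_id)) {
    abort("Design and stack subject order differ.")
  }
  m <- stack$mask
  if (!is.null(mask)) {
    mask <- as.logical(as.vector(mask))
    if (length(mask) != length(m)) abort("`mask` is not on the stack grid.")
    m <- m & mask
  }
  if (!any(m)) abort("Analysis mask is empty.")
  df <- n - ncol(X)
  if (df <= 0) abort("No residual degrees of freedom (n <= p).")

  Y <- stack$data[, m, drop = FALSE]
  fit <- glm_contrast(X, Y, design$contrast, df)

  structure(
    list(
      beta = fit$beta, sigma2 = fit$sigma2, t = fit$t, df = df,
      contrast = design$contrast, mask = m, grid = stack$grid,
      design = design
    ),
    class = "scn_fit"
  )
}

# shared OLS + contrast kernel: X (n x p) full rank, Y (n x V)
glm_contrast <- function(X, Y, contrast, df, qr_X = qr(X)) {
  beta <- qr.coef(qr_X, Y)
  res <- qr.resid(qr_X, Y)
  rss <- colSums(res^2)
  sigma2 <- rss / df
  p <- ncol(X)
  XtXinv <- matrix(0, p, p)
  XtXinv[qr_X$pivot, qr_X$pivot] <- chol2inv(qr.R(qr_X))
  cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
  est <- drop(crossprod(contrast, beta))
  # a voxel fitted exactly (or constant) has no residual scale: t undefined
  scale_ref <- pmax(colMeans(Y^2), .Machine$double.xmin)
  ok <- sigma2 > 1e-14 * scale_ref
  tval <- rep(NaN, ncol(Y))
  tval[ok] <- est[ok] / sqrt(sigma2[ok] * cvar)
  list(beta = beta, sigma2 = sigma2, t = tval, estimate = est, cvar = cvar)
}

#' @export
print.scn_fit <- function(x, ...) {
  cat(
    "<scn_fit> seed '", x$design$seed_name, "': ", sum(x$mask), " voxels, df = ",
    x$df, ", max |t| = ", format(max(abs(x$t[is.finite(x$t)]), -Inf), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Voxelwise p-values for the slope-difference contrast
#'
#' @param fit An `scn_fit`.
#' @param direction `"greater"` (CS slope > NC slope, default), `"less"`,
#'   or `"two.sided"`.
#' @return Numeric vector of p-values over in-mask voxels (NaN where t is
#'   undefined).
#' @export
scn_p_values <- function(fit, direction = c("greater", "less", "two.sided")) {
  direction <- match.arg(direction)
  switch(direction,
    greater = pt(fit$t, fit$df, lower.tail = FALSE),
    less = pt(fit$t, fit$df),
    two.sided = 2 * pt(-abs(fit$t), fit$df)
  )
}

#' Full-grid image of a fitted statistic
#'
#' @param fit An `scn_fit`.
#' @param what `"t"` (default) or a coefficient name, e.g. `"seedvol_cs"`.
#' @return 3D array on the fit's grid, NA outside the mask.
#' @export
fit_image <- function(fit, what = "t") {
  v <- rep(NA_real_, prod(fit$grid$shape))
  if (what == "t") {
    v[fit$mask] <- fit$t
  } else {
    if (!what %in% rownames(fit$beta)) abort(paste0("Unknown coefficient: ", what))
    v[fit$mask] <- fit$beta[what, ]
  }
  array(v, fit$grid$shape)
}

#' Compare subfield volumes between groups
#'
#' Fits `volume ~ group + age + gender + scanner + tiv` separately for each
#' (hemisphere, subfield), reporting the adjusted CS - NC difference and
#' BH-FDR-corrected p-values across the family of tests (25 subfields x 2
#' hemispheres = 50 by default).
#'
#' @param cohort Validated cohort tibble.
#' @param volumes Validated subfield volume table.
#' @param fdr_family `"pooled"` (default; one family across hemispheres) or
#'   `"per-hemisphere"` (two families of 25).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @return Tibble of class `subfield_comparison`: one row per
#'   (hemisphere, subfield) with `estimate` (adjusted CS - NC volume
#'   difference, mm^3), `t`, `df`, `p_value`, `p_fdr`, `significant`.
#' @export
compare_subfield_volumes <- function(cohort, volumes,
                                     fdr_family = c("pooled", "per-hemisphere"),
                                     alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  fdr_family <- match.arg(fdr_family)
  sub <- dplyr::filter(volumes, .data$subfield != "whole_thalamus")
  combos <- dplyr::distinct(sub, .data$hemisphere, .data$subfield)
  rows <- purrr::pmap(combos, function(hemisphere, subfield) {
    v <- seed_volumes(volumes, cohort, subfield, hemisphere)
    dat <- dplyr::mutate(cohort, .volume = v)
    fit <- lm(.volume ~ group + age + gender + scanner + tiv, data = dat)
    sm <- summary(fit)$coefficients
    # 'groupNC' estimates NC - CS; report the CS - NC deficit
    tibble(
      hemisphere = hemisphere, subfield = subfield,
      estimate = -sm["groupNC", "Estimate"],
      t = -sm["groupNC", "t value"],
      df = fit$df.residual,
      p_value = sm["groupNC", "Pr(>|t|)"]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (fdr_family == "pooled") {
    out$p_fdr <- fdr_bh(out$p_value)$p_adjusted
  } else {
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$hemisphere),
      p_fdr = fdr_bh(.data$p_value)$p_adjusted
    )
    out <- dplyr::ungroup(out)
  }
  out$significant <- out$p_fdr <= alpha
  class(out) <- c("subfield_comparison", class(out))
  out
}
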