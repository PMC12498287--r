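#' Spearman partial correlation
#'
#' Rank-based partial association: x, y and every covariate column are
#' average-rank transformed, the covariate ranks are regressed out of the
#' x- and y-ranks (with intercept), and the Pearson correlation of the
#' rank residuals is tested with the t approximation on
#' `n - k - 2` degrees of freedom (k = number of covariates). With no
#' covariates this reduces exactly to Spearman's rho. Incomplete rows are
#' dropped pairwise.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix/data frame of covariate
#'   columns (same length as `x`).
#' @return Tibble with `rho`, `p_value`, `n_effective`, `df`.
#' @export
spearman_partial <- function(x, y, covariates = NULL) {
  if (length(y) != length(x)) abort("`x` and `y` must have equal length.")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(x)) {
      abort("`covariates` rows must match `x`.")
    }
    storage.mode(covariates) <- "double"
  }
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  complete <- is.finite(x) & is.finite(y)
  if (k > 0L) complete <- complete & rowSums(!is.finite(covariates)) == 0L
  n <- sum(complete)
  if (n < k + 3L) abort("Too few complete cases (need n >= k + 3).")
  rx <- midrank(x[complete])
  ry <- midrank(y[complete])
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Constant x or y after pairwise deletion.")
  }
  if (k > 0L) {
    rc <- apply(covariates[complete, , drop = FALSE], 2, midrank)
    Z <- cbind(1, rc)
    qz <- qr(Z)
    rx <- qr.resid(qz, rx)
    ry <- qr.resid(qz, ry)
    if (sd(rx) == 0 || sd(ry) == 0) {
      abort("x or y fully explained by covariates on the rank scale.")
    }
  }
  rho <- cor(rx, ry)
  df <- n - k - 2L
  tt <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  tibble(rho = rho, p_value = 2 * pt(-abs(tt), df), n_effective = n, df = df)
}

#' Per-subject seed SCN measure
#'
#' The group-level covariance model has no per-subject network scalar; this
#' operationalizes one. The default (`"crossterm"`) is the subject's
#' ROI-mean GMV multiplied by the subject's z-scored seed volume — the
#' subject-level cross-term whose group average is the covariance slope the
#' GLM estimates. `"roi_mean"` uses the ROI-mean GMV alone. Both are
#' pluggable so the interpretive choice stays isolated here.
#'
#' @param roi_means Tibble from [extract_mean_gmv()].
#' @param seed_volumes Seed volumes aligned to `roi_means` rows.
#' @param method `"crossterm"` (default) or `"roi_mean"`.
#' @param aggregate Combine the ROI columns into one measure per subject by
#'   their mean (default `TRUE`); otherwise one measure per ROI.
#' @return Tibble: `subject_id` plus measure column(s).
#' @export
scn_subject_measure <- function(roi_means, seed_volumes,
                                method = c("crossterm", "roi_mean"),
                                aggregate = TRUE) {
  method <- match.arg(method)
  roi_cols <- setdiff(names(roi_means), "subject_id")
  M <- as.matrix(roi_means[, roi_cols, drop = FALSE])
  if (method == "crossterm") {
    M <- M * zscore(seed_volumes)
  }
  if (aggregate) {
    tibble(subject_id = roi_means$subject_id, scn_measure = rowMeans(M))
  } else {
    dplyr::bind_cols(tibble(subject_id = roi_means$subject_id), as_tibble(M))
  }
}

#' Screen seed-level SCN measures against clinical scores
#'
#' Runs [spearman_partial()] for every (seed measure, clinical metric)
#' pair within one group, controlling for age, gender, and scanner
#' (configurable), BH-FDR-corrects the whole grid, and tallies the looser
#' uncorrected-p tier per metric and per seed.
#'
#' @param measures Tibble of per-subject seed measures: `subject_id` plus
#'   one column per seed.
#' @param cohort Validated cohort tibble (supplies metrics + covariates).
#' @param group Which group to screen (`"CS"` or `"NC"`).
#' @param metrics Clinical columns to use (default: available ones among
#'   FMA, RAVLT_SR, RAVLT_LR, N_ACC, N_RT, S_ACC, S_RT).
#' @param covariates Cohort columns to control for (default age, gender,
#'   scanner; factors are expanded to dummies).
#' @param q FDR level (default 0.05).
#' @param uncorrected_alpha Looser exploratory threshold (default 0.05).
#' @return Tibble of class `scn_corr_screen`: `seed`, `metric`, `rho`,
#'   `p_value`, `p_fdr`, `n_effective`, `fdr_significant`,
#'   `uncorrected_significant`.
#' @export
correlation_screen <- function(measures, cohort, group = "CS",
                               metrics = NULL,
                               covariates = c("age", "gender", "scanner"),
                               q = 0.05, uncorrected_alpha = 0.05) {
  cohort <- validate_cohort(cohort, require_both_groups = FALSE)
  if (is.null(metrics)) {
    metrics <- intersect(CLINICAL_SCORES, names(cohort))
  }
  miss <- setdiff(metrics, names(cohort))
  if (length(miss)) abort(paste0("Metrics absent from cohort: ", paste(miss, collapse = ", ")))
  sub <- dplyr::filter(cohort, .data$group == !!group)
  if (!nrow(sub)) abort(paste0("No subjects in group ", group, "."))
  hit <- match(sub$subject_id, measures$subject_id)
  if (anyNA(hit)) abort("Measures missing for some subjects in the group.")
  meas <- measures[hit, , drop = FALSE]
  seed_cols <- setdiff(names(meas), "subject_id")

  cov_mat <- NULL
  if (length(covariates)) {
    pieces <- lapply(covariates, function(v) {
      col <- sub[[v]]
      if (is.factor(col) || is.character(col)) {
        f <- droplevels(factor(col))
        if (nlevels(f) < 2L) return(NULL)  # constant within group: nothing to control
        d <- vapply(levels(f)[-1], function(l) as.numeric(f == l), numeric(nrow(sub)))
        colnames(d) <- paste0(v, "_", levels(f)[-1])
        d
      } else {
        matrix(as.numeric(col), ncol = 1, dimnames = list(NULL, v))
      }
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    if (length(pieces)) cov_mat <- do.call(cbind, pieces)
  }

  grid_rows <- tidyr::expand_grid(seed = seed_cols, metric = metrics)
  rows <- purrr::pmap(grid_rows, function(seed, metric) {
    res <- tryCatch(
      spearman_partial(meas[[seed]], sub[[metric]], cov_mat),
      error = function(e) tibble(rho = NA_real_, p_value = NA_real_,
                                 n_effective = NA_integer_, df = NA_integer_)
    )
    tibble(
      seed = seed, metric = metric, rho = res$rho,
      p_value = res$p_value, n_effective = res$n_effective
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_fdr <- fdr_bh(out$p_value, q = q)$p_adjusted
  out$fdr_significant <- !is.na(out$p_fdr) & out$p_fdr <= q
  out$uncorrected_significant <- !is.na(out$p_value) & out$p_value < uncorrected_alpha
  attr(out, "group") <- group
  attr(out, "q") <- q
  attr(out, "uncorrected_alpha") <- uncorrected_alpha
  class(out) <- c("scn_corr_screen", class(out))
  out
}

#' Tally uncorrected associations per metric or per seed
#'
#' The "N = ..." style summaries of an exploratory screen: how many
#' uncorrected associations each clinical metric (or each seed) attains.
#'
#' @param screen An `scn_corr_screen` tibble.
#' @param by `"metric"` or `"seed"`.
#' @return Tibble with the grouping column and `n_uncorrected`,
#'   `n_fdr`.
#' @export
screen_counts <- function(screen, by = c("metric", "seed")) {
  by <- match.arg(by)
  out <- dplyr::summarise(
    dplyr::group_by(screen, dplyr::across(dplyr::all_of(by))),
    n_uncorrected = sum(.data$uncorrected_significant, na.rm = TRUE),
    n_fdr = sum(.data$fdr_significant, na.rm = TRUE),
    .groups = "drop"
  )
  dplyr::arrange(out, dplyr::desc(.data$n_uncorrected))
}
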