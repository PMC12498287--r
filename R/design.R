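#' Build the seed-covariance design matrix
#'
#' Encodes the two-group structural-covariance model
#' `GMV = b1*Label_cs + b2*Label_nc + b3*SeedVol_cs + b4*SeedVol_nc +
#' sum(bx * Confounders) + e`: group indicator columns play the role of
#' group-specific intercepts, the z-scored seed volume enters split into two
#' group-specific slope columns (zero in the other group), and age
#' (mean-centred), gender (male = 0), scanner (K - 1 dummies, reference =
#' first level alphabetically) and mean-centred TIV are additive confounders.
#' The difference of the two slope coefficients is the group difference in
#' covariance connectivity.
#'
#' @param cohort Validated cohort tibble.
#' @param seed_volumes Numeric seed (subfield) volumes aligned to cohort rows.
#' @param zscore_scope `"pooled"` (default) z-scores the seed volume over
#'   the whole sample; `"per-group"` standardizes within each group
#'   (changes the meaning of the slope contrast — exposed for sensitivity
#'   analysis only).
#' @param seed_name Label stored with the design (bookkeeping).
#' @return Object of class `scn_design`: list with `X` (n x p design
#'   matrix), `contrast` (the slope-difference contrast vector),
#'   `seed_cols`, `cohort`, `seed_name`, `zscore_scope`.
#' @export
build_scn_design <- function(cohort, seed_volumes,
                             zscore_scope = c("pooled", "per-group"),
                             seed_name = "seed") {
  cohort <- validate_cohort(cohort)
  zscore_scope <- match.arg(zscore_scope)
  n <- nrow(cohort)
  if (length(seed_volumes) != n) {
    abort("`seed_volumes` must align with cohort rows.")
  }
  if (anyNA(seed_volumes)) abort("`seed_volumes` must be complete.")
  is_cs <- cohort$group == "CS"
  z <- if (zscore_scope == "pooled") {
    zscore(seed_volumes)
  } else {
    out <- numeric(n)
    out[is_cs] <- zscore(seed_volumes[is_cs])
    out[!is_cs] <- zscore(seed_volumes[!is_cs])
    out
  }
  X <- cbind(
    label_cs = as.numeric(is_cs),
    label_nc = as.numeric(!is_cs),
    seedvol_cs = z * is_cs,
    seedvol_nc = z * !is_cs,
    age = cohort$age - mean(cohort$age),
    gender = as.numeric(cohort$gender == "female"),
    tiv = cohort$tiv - mean(cohort$tiv)
  )
  lev <- levels(cohort$scanner)
  if (length(lev) > 1L) {
    dum <- vapply(lev[-1], function(l) as.numeric(cohort$scanner == l), numeric(n))
    colnames(dum) <- paste0("scanner_", lev[-1])
    X <- cbind(X[, 1:6], dum, tiv = X[, "tiv"])
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0(
      "Design matrix is rank deficient; offending column(s): ",
      paste(dropped, collapse = ", ")
    ))
  }
  contrast <- numeric(ncol(X))
  names(contrast) <- colnames(X)
  contrast[c("seedvol_cs", "seedvol_nc")] <- c(1, -1)
  structure(
    list(
      X = X, contrast = contrast, seed_cols = c(3L, 4L),
      cohort = cohort, seed_name = seed_name, zscore_scope = zscore_scope
    ),
    class = "scn_design"
  )
}

#' @export
print.scn_design <- function(x, ...) {
  cat(
    "<scn_design> ", nrow(x$X), " subjects x ", ncol(x$X), " columns (seed: ",
    x$seed_name, ")\n",
    sep = ""
  )
  invisible(x)
}
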