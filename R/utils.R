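#' Z-score a vector
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (n - 1
#' denominator), the scaling applied to seed volumes before they enter the
#' covariance design.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @return Standardized numeric vector.
#' @examples
#' zscore(c(1, 2, 3))  # -1 0 1
#' @export
zscore <- function(x) {
  if (length(x) < 2L) abort("Need at least 2 values to z-score.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("Cannot z-score a constant vector.")
  (x - mean(x)) / s
}

# average-rank transform (midranks for ties), NAs kept as NA
midrank <- function(x) {
  rank(x, ties.method = "average", na.last = "keep")
}
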