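#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control; adjusted p-values are monotone and
#' a test is rejected when its adjusted value is at most `q`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed,
#'   passed through).
#' @param q FDR level for the rejection flags (default 0.05).
#' @return Tibble with `p_value`, `p_adjusted`, `rejected`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  chk <- p_values[!is.na(p_values)]
  if (any(chk < 0 | chk > 1)) abort("p-values must lie in [0, 1].")
  adj <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, p_adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `min(1, p * m)` where `m` may exceed the number of p-values supplied
#' (e.g. when only a subset of a test family is being reported).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param family_size Family size `m`; must be at least
#'   `length(p_values)` and at least 1.
#' @return Numeric vector of adjusted p-values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (family_size < 1) abort("`family_size` must be >= 1.")
  if (family_size < length(p_values)) {
    abort("`family_size` must be at least the number of p-values.")
  }
  chk <- p_values[!is.na(p_values)]
  if (any(chk < 0 | chk > 1)) abort("p-values must lie in [0, 1].")
  pmin(1, p_values * family_size)
}
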