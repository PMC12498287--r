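#' One-sample Kolmogorov-Smirnov normality screen
#'
#' Tests a sample against a normal distribution with the sample's own mean
#' and SD — the conventional screen used to route each demographic or
#' clinical variable to a t-test (normal) or Mann-Whitney U (non-normal).
#' Note the estimated parameters make the test conservative (Lilliefors
#' situation); it is used here as a routing heuristic, not strict inference.
#'
#' @param values Numeric vector, n >= 5, non-constant; NAs dropped.
#' @return Tibble with `statistic`, `p_value`, `n`.
#' @export
ks_normality <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 5L) abort("Need at least 5 finite values.")
  if (sd(x) == 0) abort("Cannot screen a constant sample for normality.")
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value, n = length(x))
}

#' Group summary (n, mean, SD)
#'
#' @param values Numeric vector (NAs dropped).
#' @return Tibble with `n`, `mean`, `sd` (sample SD, n - 1 denominator).
#' @export
group_summary <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 2L) abort("Need at least 2 finite values.")
  tibble(n = length(x), mean = mean(x), sd = sd(x))
}

#' Welch two-sample t-test from group summaries
#'
#' Unequal-variance t with Welch-Satterthwaite degrees of freedom, computed
#' directly from per-group (n, mean, SD) so published summary rows can be
#' re-tested. A pooled-variance variant is available by flag.
#'
#' @param a,b Data frames/tibbles with columns `n`, `mean`, `sd` (one row),
#'   e.g. from [group_summary()].
#' @param pooled Use the pooled-variance (Student) form instead of Welch.
#' @return Tibble with `t`, `df`, `p_value` (two-sided), `mean_diff`.
#' @examples
#' welch_t_from_summaries(
#'   tibble::tibble(n = 45, mean = 42.778, sd = 10.396),
#'   tibble::tibble(n = 93, mean = 49.527, sd = 8.305)
#' )
#' @export
welch_t_from_summaries <- function(a, b, pooled = FALSE) {
  for (g in list(a, b)) {
    if (!all(c("n", "mean", "sd") %in% names(g)) || nrow(g) != 1L) {
      abort("Summaries need one row with columns n, mean, sd.")
    }
    if (g$n < 2 || g$sd < 0) abort("Invalid summary: need n >= 2 and sd >= 0.")
  }
  if (a$sd == 0 && b$sd == 0) abort("Both group SDs are zero.")
  d <- a$mean - b$mean
  if (pooled) {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- d / se
  tibble(t = t, df = df, p_value = 2 * pt(-abs(t), df), mean_diff = d)
}

#' Pearson chi-square on a 2x2 table
#'
#' Without continuity correction, the form conventional for group-by-gender
#' tables.
#'
#' @param table 2x2 numeric matrix of counts with all row and column
#'   margins positive.
#' @return Tibble with `chisq`, `df` (= 1), `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(27, 50, 18, 43), 2))
#' @export
chi_square_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) abort("Need a 2x2 table.")
  if (any(m < 0)) abort("Counts must be non-negative.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("All row and column margins must be positive.")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(chisq = unname(ct$statistic), df = 1L, p_value = ct$p.value)
}

#' Mann-Whitney U with tie-corrected normal approximation
#'
#' Reports U for the first sample, the tie-corrected Z (positive when the
#' first sample's rank-sum exceeds its null expectation), and the
#' two-sided normal-approximation p-value.
#'
#' @param a,b Numeric vectors (NAs dropped), each non-empty.
#' @return Tibble with `U`, `Z`, `p_value`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (!length(a) || !length(b)) abort("Both samples must be non-empty.")
  na <- length(a)
  nb <- length(b)
  r <- midrank(c(a, b))
  ra <- sum(r[seq_len(na)])
  U <- ra - na * (na + 1) / 2
  N <- na + nb
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) {
    # all values tied: no evidence either way
    return(tibble(U = U, Z = 0, p_value = 1, n_a = na, n_b = nb))
  }
  Z <- (U - na * nb / 2) / sqrt(v)
  tibble(U = U, Z = Z, p_value = 2 * pnorm(-abs(Z)), n_a = na, n_b = nb)
}

#' Demographic / clinical comparison table
#'
#' For each continuous variable: KS normality screen on the pooled sample,
#' then Welch t (normal) or Mann-Whitney U (non-normal); gender compared by
#' 2x2 chi-square. Reproduces the layout of a study demographics table.
#'
#' @param cohort Validated cohort tibble.
#' @param variables Continuous columns to compare (default age + available
#'   clinical scores).
#' @param normality_alpha KS p-value below which a variable is routed to
#'   the rank test (default 0.05).
#' @return Tibble with one row per variable: group summaries, the test
#'   used, statistic and p-value.
#' @export
demographics_table <- function(cohort, variables = NULL,
                               normality_alpha = 0.05) {
  cohort <- validate_cohort(cohort)
  if (is.null(variables)) {
    variables <- intersect(c("age", CLINICAL_SCORES), names(cohort))
  }
  cs <- dplyr::filter(cohort, .data$group == "CS")
  nc <- dplyr::filter(cohort, .data$group == "NC")
  rows <- purrr::map(variables, function(v) {
    x <- cs[[v]]
    y <- nc[[v]]
    pooled <- c(x, y)
    ksp <- tryCatch(ks_normality(pooled)$p_value, error = function(e) NA_real_)
    sa <- group_summary(x)
    sb <- group_summary(y)
    if (!is.na(ksp) && ksp >= normality_alpha) {
      tt <- welch_t_from_summaries(sa, sb)
      tibble(
        variable = v, test = "welch_t",
        cs_n = sa$n, cs_mean = sa$mean, cs_sd = sa$sd,
        nc_n = sb$n, nc_mean = sb$mean, nc_sd = sb$sd,
        statistic = tt$t, p_value = tt$p_value, ks_p = ksp
      )
    } else {
      mw <- mann_whitney(x[is.finite(x)], y[is.finite(y)])
      tibble(
        variable = v, test = "mann_whitney",
        cs_n = sa$n, cs_mean = sa$mean, cs_sd = sa$sd,
        nc_n = sb$n, nc_mean = sb$mean, nc_sd = sb$sd,
        statistic = mw$Z, p_value = mw$p_value, ks_p = ksp
      )
    }
  })
  cont <- dplyr::bind_rows(rows)
  tab <- table(cohort$group, cohort$gender)
  chi <- chi_square_2x2(matrix(as.numeric(tab), 2))
  gender_row <- tibble(
    variable = "gender", test = "chi_square",
    cs_n = sum(tab["CS", ]), cs_mean = NA_real_, cs_sd = NA_real_,
    nc_n = sum(tab["NC", ]), nc_mean = NA_real_, nc_sd = NA_real_,
    statistic = chi$chisq, p_value = chi$p_value, ks_p = NA_real_
  )
  dplyr::bind_rows(gender_row, cont)
}
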