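#' Case-control allele-count test in observed/expected form
#'
#' The 2x2 allele-count table (allele 1/2 by case/control) tested with the
#' hypergeometric (Mantel-Haenszel style) chi-square: the observed count is
#' the allele-1 count in cases, the expected count comes from the margins,
#' and the variance is `r1 r2 c1 c2 / (N^2 (N - 1))` with `N` the total
#' allele count. This equals the Pearson 2x2 chi-square times `(N-1)/N`.
#' Returning the (O, E, Var) triple rather than only the chi-square is what
#' allows pooling with other strata.
#'
#' @param a1_case,a2_case Allele 1/2 counts in cases.
#' @param a1_ctrl,a2_ctrl Allele 1/2 counts in controls.
#' @return A `stratum_stats` list: `O`, `E`, `Var`, `chi2`, `p_value`,
#'   `source`, `defined`. With a zero margin the statistic is undefined
#'   (`defined = FALSE`, `chi2 = NA`) and the marker should be skipped.
#' @examples
#' case_control_allele_test(10, 5, 5, 10)
#' @export
case_control_allele_test <- function(a1_case, a2_case, a1_ctrl, a2_ctrl) {
  cnt <- c(a1_case, a2_case, a1_ctrl, a2_ctrl)
  if (anyNA(cnt) || any(cnt < 0)) stop("allele counts must be non-negative")
  N <- sum(cnt)
  r1 <- a1_case + a1_ctrl; r2 <- a2_case + a2_ctrl   # allele margins
  c1 <- a1_case + a2_case; c2 <- a1_ctrl + a2_ctrl   # group margins
  if (N <= 1 || r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(stratum_stats(NA_real_, NA_real_, NA_real_, "case_control",
                         defined = FALSE))
  O <- a1_case
  E <- r1 * c1 / N
  Var <- r1 * r2 * c1 * c2 / (N^2 * (N - 1))
  stratum_stats(O, E, Var, "case_control")
}

#' dTDT transmissions as a pooling stratum
#'
#' Casts the dTDT's pooled pseudo-counts as an observed/expected/variance
#' triple on a 1x2 table — `O = sum(b)`, `E = (b + c)/2`,
#' `Var = (b + c)/4` — so its chi-square `(b - c)^2 / (b + c)` can enter a
#' Mantel-Haenszel combination alongside a case-control stratum.
#'
#' @param sum_b,sum_c Pooled allele-1 / allele-2 transmission pseudo-counts.
#' @return A `stratum_stats` list (see [case_control_allele_test()]).
#' @examples
#' dtdt_stratum_stats(15, 5)   # chi2 = 5, identical to the dTDT statistic
#' @export
dtdt_stratum_stats <- function(sum_b, sum_c) {
  if (is.na(sum_b) || is.na(sum_c) || sum_b < 0 || sum_c < 0)
    stop("pseudo-counts must be non-negative")
  tot <- sum_b + sum_c
  if (tot == 0)
    return(stratum_stats(NA_real_, NA_real_, NA_real_, "dtdt",
                         defined = FALSE))
  stratum_stats(sum_b, tot / 2, tot / 4, "dtdt")
}

stratum_stats <- function(O, E, Var, source, defined = TRUE) {
  chi2 <- if (defined && Var > 0) (O - E)^2 / Var else NA_real_
  structure(list(O = O, E = E, Var = Var, chi2 = chi2,
                 p_value = if (is.na(chi2)) NA_real_ else
                   stats::pchisq(chi2, 1, lower.tail = FALSE),
                 source = source, defined = defined && Var > 0),
            class = "stratum_stats")
}

#' Mantel-Haenszel combination of test strata
#'
#' Pools observed-minus-expected differences and variances across strata:
#' `chi2 = (sum(O - E))^2 / sum(Var)`, 1 df. Used here to combine the
#' case-control and dTDT strata for a SNP, but any number of strata with
#' defined (O, E, Var) can be pooled. Effects in opposite directions
#' cancel, the known Mantel-Haenszel behavior.
#'
#' @param strata A list of `stratum_stats` objects; undefined strata are
#'   dropped.
#' @return A list: `chi2`, `p_value`, `direction` (sign of `sum(O - E)`),
#'   `n_strata` used, `defined`.
#' @examples
#' mantel_haenszel_combine(list(dtdt_stratum_stats(15, 5),
#'                              case_control_allele_test(10, 5, 5, 10)))
#' @export
mantel_haenszel_combine <- function(strata) {
  if (inherits(strata, "stratum_stats")) strata <- list(strata)
  strata <- Filter(function(s) isTRUE(s$defined), strata)
  if (!length(strata))
    return(list(chi2 = NA_real_, p_value = NA_real_, direction = NA_real_,
                n_strata = 0L, defined = FALSE))
  d <- sum(vapply(strata, function(s) s$O - s$E, numeric(1)))
  v <- sum(vapply(strata, function(s) s$Var, numeric(1)))
  if (v <= 0)
    return(list(chi2 = NA_real_, p_value = NA_real_, direction = NA_real_,
                n_strata = length(strata), defined = FALSE))
  chi2 <- d^2 / v
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, 1, lower.tail = FALSE),
       direction = sign(d), n_strata = length(strata), defined = TRUE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (at least 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 19)  # 0.0026
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(m) || m < 1 || m != round(m))
    stop("m must be a positive integer")
  alpha / m
}

#' Mean and sample variance of a p-value column
#'
#' @param pvalues Numeric vector of at least two p-values.
#' @return A list with `mean` (denominator `n`) and `variance`
#'   (denominator `n - 1`).
#' @export
summarize_pvalues <- function(pvalues) {
  if (length(pvalues) < 2) stop("need at least two p-values")
  if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  list(mean = mean(pvalues), variance = stats::var(pvalues))
}

#' Expected/observed quantile coordinates for a QQ plot
#'
#' Observed coordinates are the sorted `-log10(p)` in decreasing order;
#' expected coordinates use the plotting positions `(i - 0.5)/n` for rank
#' `i`, also as `-log10`. Points far above the diagonal flag inflation of
#' the test (e.g. from population stratification).
#'
#' @param pvalues Non-empty numeric vector of p-values in (0, 1\].
#' @return A `data.frame` with columns `expected` and `observed`.
#' @examples
#' qq_coordinates((1:10 - 0.5) / 10)  # exactly on the diagonal
#' @export
qq_coordinates <- function(pvalues) {
  if (!length(pvalues)) stop("need at least one p-value")
  if (anyNA(pvalues) || any(pvalues <= 0))
    stop("p-values must be strictly positive")
  n <- length(pvalues)
  data.frame(expected = -log10((seq_len(n) - 0.5) / n),
             observed = sort(-log10(pvalues), decreasing = TRUE))
}
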