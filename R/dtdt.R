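#' Per-trio transmission pseudo-counts from dosage probabilities
#'
#' For each trio, computes the expected number of allele-1 transmissions
#' (`b`) and allele-2 transmissions (`c`) from heterozygous parents to the
#' affected child, generalizing the classic TDT counts to genotype dosages.
#' The closed form is `b_i = 2 p_c11 + p_c12 - p_f11 - p_m11` and
#' `c_i = (p_f12 + p_m12) - b_i`, so `b_i + c_i` always equals the
#' heterozygosity mass `s_i = p_f12 + p_m12` (the informativeness of the
#' trio).
#'
#' Dosage sets that are inconsistent with any transmission probability in
#' \[0, 1\] (e.g. Mendelian-impossible hard genotypes) can yield raw
#' pseudo-counts outside \[0, s_i\]; by default these are clamped to the
#' valid range, preserving `b_i + c_i = s_i`, and flagged.
#'
#' @param trios A trio dosage set, see [trio_dosage_set()].
#' @param clamp Clamp out-of-range pseudo-counts to `[0, s_i]` (default
#'   `TRUE`). Set `FALSE` to inspect raw values for diagnostics.
#' @return A `data.frame` with columns `trio_id`, `marker_id`, `b`, `c`,
#'   `s` and logical `clamped`.
#' @seealso [dtdt_statistic()] to pool increments into the marker test.
#' @examples
#' tr <- trio_dosage_set("t1", "rs1",
#'                       father = genotype_dosage(0, 1, 0),
#'                       mother = genotype_dosage(1, 0, 0),
#'                       child  = genotype_dosage(1, 0, 0))
#' trio_increments(tr)   # b = 1: the het father transmitted allele 1
#' @export
trio_increments <- function(trios, clamp = TRUE) {
  stopifnot(is.data.frame(trios))
  s <- trios$f12 + trios$m12
  b <- 2 * trios$c11 + trios$c12 - trios$f11 - trios$m11
  cc <- s - b
  clamped <- rep(FALSE, length(b))
  if (clamp) {
    tol <- 1e-9  # round-off from consistent posteriors is not inconsistency
    bad <- b < -tol | b > s + tol
    if (any(bad))
      warning(sum(bad), " trio(s) had pseudo-counts outside [0, s]; clamped")
    clip <- bad | b < 0 | b > s
    b[clip] <- pmin(pmax(b[clip], 0), s[clip])
    cc[clip] <- s[clip] - b[clip]
    clamped[bad] <- TRUE
  }
  zero <- s <= 0
  b[zero] <- 0
  cc[zero] <- 0
  data.frame(trio_id = trios$trio_id, marker_id = trios$marker_id,
             b = b, c = cc, s = s, clamped = clamped,
             stringsAsFactors = FALSE)
}

#' Dosage Transmission/Disequilibrium Test
#'
#' Pools per-trio transmission pseudo-counts into the dTDT chi-square for a
#' marker: `chi2 = (sum(b) - sum(c))^2 / (sum(b) + sum(c))`, referred to a
#' 1-df chi-square distribution. The estimated probability that a
#' heterozygous parent transmits allele 1 is
#' `t_hat = sum(b) / (sum(b) + sum(c))`.
#'
#' When every trio has hard (0/1) Mendelian-consistent dosages, the
#' statistic reduces exactly to the classic TDT on counted transmissions.
#'
#' @param increments Output of [trio_increments()].
#' @param marker_id Marker label for the result row (default: taken from
#'   the increments).
#' @return A one-row `data.frame`: `marker_id`, `sum_b`, `sum_c`, `t_hat`
#'   (`NA` when no informative mass), `chi2`, `p_value`, `neglog10_p`
#'   (computed on the log scale, exact even when `p_value` underflows),
#'   `n_trios`, `n_informative`.
#' @examples
#' tr <- trio_dosage_set(c("t1", "t2"), "rs1",
#'                       father = rbind(c(0, 1, 0), c(0, 1, 0)),
#'                       mother = rbind(c(1, 0, 0), c(1, 0, 0)),
#'                       child  = rbind(c(1, 0, 0), c(0, 1, 0)))
#' dtdt_statistic(trio_increments(tr))
#' @export
dtdt_statistic <- function(increments, marker_id = NULL) {
  if (is.null(marker_id))
    marker_id <- if (nrow(increments)) increments$marker_id[1] else NA_character_
  sum_b <- sum(increments$b)
  sum_c <- sum(increments$c)
  chisq_result(marker_id, sum_b, sum_c,
               n_trios = nrow(increments),
               n_informative = sum(increments$s > 0))
}

#' Classic TDT on hard transmission counts
#'
#' The original trio test: `b` transmissions of allele 1 and `c` of allele 2
#' from heterozygous parents are compared against the 50:50 null with
#' `chi2 = (b - c)^2 / (b + c)`, 1 df.
#'
#' @param b Count of allele-1 transmissions from heterozygous parents.
#' @param c Count of allele-2 transmissions.
#' @param marker_id Optional marker label.
#' @return Same shape as [dtdt_statistic()].
#' @examples
#' classic_tdt(15, 5)  # chi2 = 5
#' @export
classic_tdt <- function(b, c, marker_id = NA_character_) {
  if (length(b) != 1 || length(c) != 1 || is.na(b) || is.na(c) ||
      b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("b and c must be non-negative integer counts")
  chisq_result(marker_id, b, c, n_trios = NA_integer_,
               n_informative = NA_integer_)
}

# shared 1-df chi-square result row for (sum_b, sum_c) transmission tests
chisq_result <- function(marker_id, sum_b, sum_c, n_trios, n_informative) {
  tot <- sum_b + sum_c
  if (tot > 0) {
    chi2 <- (sum_b - sum_c)^2 / tot
    t_hat <- sum_b / tot
  } else {
    chi2 <- 0
    t_hat <- NA_real_
  }
  lp <- stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE)
  data.frame(marker_id = as.character(marker_id),
             sum_b = sum_b, sum_c = sum_c, t_hat = t_hat, chi2 = chi2,
             p_value = max(exp(lp), .Machine$double.xmin),
             neglog10_p = -lp / log(10),
             n_trios = n_trios, n_informative = n_informative,
             stringsAsFactors = FALSE)
}
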