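#' Infer trio dosage sets for simulated trios
#'
#' For each simulated trio the child's SNP genotype is observed and both
#' parents are un-genotyped, so the parental posteriors depend only on the
#' child genotype and the founder allele frequency. The three possible
#' posteriors are computed once by exact enumeration
#' ([parental_posterior()]) and assigned by lookup.
#'
#' @param trios Output of [simulate_trio_set()].
#' @param q1 Founder allele-1 frequency used as the Hardy-Weinberg prior
#'   (for simulated data, the model's population frequency).
#' @param marker_id Marker label.
#' @return A trio dosage set (see [trio_dosage_set()]), one row per trio.
#' @export
infer_trio_dosages <- function(trios, q1, marker_id = "snp") {
  idx <- genotype_index(trios$child_snp)
  arch <- lapply(GENOTYPES, parental_posterior, q1 = q1,
                 marker_id = marker_id)
  pcols <- c("f11", "f12", "f22", "m11", "m12", "m22",
             "c11", "c12", "c22")
  arch_m <- do.call(rbind, lapply(arch, function(a) as.matrix(a[, pcols])))
  out <- data.frame(trio_id = trios$trio_id,
                    marker_id = rep(marker_id, nrow(trios)),
                    arch_m[idx, , drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Run the dTDT on a simulated trio set
#'
#' Convenience wrapper: infer parental dosages, compute per-trio
#' transmission pseudo-counts, and pool them into the marker statistic.
#'
#' @inheritParams infer_trio_dosages
#' @return A one-row `data.frame`, see [dtdt_statistic()].
#' @export
dtdt_run <- function(trios, q1, marker_id = "snp") {
  dtdt_statistic(trio_increments(infer_trio_dosages(trios, q1, marker_id)),
                 marker_id)
}

#' Replicated power run of the simulate-infer-test pipeline
#'
#' Simulates `reps` independent sets of `n` trios under the model, infers
#' parental dosages at the model's population allele frequency, and
#' applies the dTDT to each set. Replicate seeds are derived from `seed`
#' by the documented splitting rule.
#'
#' @param model A [disease_model()].
#' @param n Trios per replicate.
#' @param reps Number of replicates.
#' @param seed Integer master seed.
#' @return A `data.frame` with one row per replicate: `rep`, `chi2`,
#'   `p_value`, `neglog10_p`.
#' @export
dtdt_power_run <- function(model, n, reps, seed) {
  rows <- lapply(seq_len(reps), function(r) {
    trios <- simulate_trio_set(model, n, derive_subseed(seed, r))
    res <- dtdt_run(trios, model$q1)
    data.frame(rep = r, chi2 = res$chi2, p_value = res$p_value,
               neglog10_p = res$neglog10_p)
  })
  do.call(rbind, rows)
}

#' Simulate complete-genotype trios under a transmission probability
#'
#' Null/alternative generator with hard genotypes: parents are drawn from
#' Hardy-Weinberg at `q1`; each parent transmits, if homozygous, its only
#' allele, and if heterozygous, allele 1 with probability `t`. `t = 0.5`
#' is the TDT null regardless of the allele frequency.
#'
#' @param n Number of trios.
#' @param q1 Allele-1 frequency.
#' @param t Transmission probability of allele 1 from heterozygotes.
#' @param seed Integer seed.
#' @return A trio dosage set with 0/1 dosages.
#' @export
simulate_hard_trios <- function(n, q1, t = 0.5, seed = 1) {
  with_seed(seed, {
    draw_parent <- function() {
      a1 <- stats::rbinom(n, 1, q1)   # allele-1 indicator, first allele
      a2 <- stats::rbinom(n, 1, q1)
      cbind(n1 = a1 + a2)             # number of allele-1 copies: 0,1,2
    }
    f <- draw_parent(); m <- draw_parent()
    transmit <- function(n1) {
      tr <- ifelse(n1 == 2, 1L, ifelse(n1 == 0, 0L,
                                       stats::rbinom(n, 1, t)))
      tr  # 1 = transmitted allele 1
    }
    tf <- transmit(f[, 1]); tm <- transmit(m[, 1])
    child_n1 <- tf + tm
    hard <- function(n1) cbind(n1 == 2, n1 == 1, n1 == 0) * 1
    trio_dosage_set(sprintf("trio%d", seq_len(n)), "snp",
                    father = hard(f[, 1]), mother = hard(m[, 1]),
                    child = hard(child_n1))
  })
}

#' Type-I error calibration of the TDT chi-square
#'
#' Simulates replicates of complete-genotype trios under the `t = 0.5`
#' null and reports the fraction rejected at `alpha`, which should match
#' `alpha` up to binomial noise.
#'
#' @param reps Number of replicates.
#' @param n Trios per replicate.
#' @param q1 Allele-1 frequency.
#' @param alpha Nominal test level.
#' @param seed Integer master seed.
#' @return A list: `rejection_rate`, `p_values`, `alpha`, binomial
#'   standard error `se`.
#' @export
tdt_null_calibration <- function(reps = 1000, n = 500, q1 = 0.5,
                                 alpha = 0.05, seed = 1) {
  pv <- vapply(seq_len(reps), function(r) {
    trios <- simulate_hard_trios(n, q1, t = 0.5,
                                 seed = derive_subseed(seed, r))
    dtdt_statistic(trio_increments(trios))$p_value
  }, numeric(1))
  list(rejection_rate = mean(pv < alpha), p_values = pv, alpha = alpha,
       se = sqrt(alpha * (1 - alpha) / reps))
}

#' Joint case-control + dTDT + Mantel-Haenszel results for one marker
#'
#' Computes the three statistics for one SNP and assembles a results row
#' in the standard output layout (see [write_results()]).
#'
#' @param marker Marker name.
#' @param a1_case,a2_case,a1_ctrl,a2_ctrl Case-control allele counts.
#' @param sum_b,sum_c Pooled dTDT pseudo-counts.
#' @param chr,gm,pm Optional map coordinates.
#' @param n_informative Optional informative-trio count.
#' @return A one-row `data.frame` in [write_results()] column layout.
#' @export
combined_marker_test <- function(marker, a1_case, a2_case, a1_ctrl, a2_ctrl,
                                 sum_b, sum_c, chr = NA, gm = NA, pm = NA,
                                 n_informative = NA) {
  cc <- case_control_allele_test(a1_case, a2_case, a1_ctrl, a2_ctrl)
  td <- dtdt_stratum_stats(sum_b, sum_c)
  mh <- mantel_haenszel_combine(list(cc, td))
  data.frame(marker = marker, chr = chr, gm = gm, pm = pm,
             cc_chi2 = cc$chi2, cc_p = cc$p_value,
             dtdt_chi2 = td$chi2, dtdt_p = td$p_value,
             mh_chi2 = mh$chi2, mh_p = mh$p_value,
             direction = mh$direction, n_informative = n_informative,
             stringsAsFactors = FALSE)
}
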