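#' Genotype dosage triple
#'
#' A dosage is the posterior probability distribution over the three
#' genotypes of a biallelic marker for one individual, usually produced by
#' family-based genotype inference or imputation. Alleles are coded 1 and 2,
#' so the genotypes are 1/1, 1/2 and 2/2.
#'
#' @param p11 Probability of genotype 1/1.
#' @param p12 Probability of genotype 1/2.
#' @param p22 Probability of genotype 2/2.
#' @return A named numeric vector `c(p11, p12, p22)`.
#' @examples
#' genotype_dosage(0.2, 0.5, 0.3)
#' genotype_dosage(1, 0, 0)   # a hard 1/1 call
#' @export
genotype_dosage <- function(p11, p12, p22) {
  p <- c(p11 = p11, p12 = p12, p22 = p22)
  if (anyNA(p) || any(p < -1e-9) || any(p > 1 + 1e-9))
    stop("dosage components must lie in [0, 1]")
  if (abs(sum(p) - 1) > 1e-9)
    stop("dosage components must sum to 1 (got ", format(sum(p)), ")")
  pmin(pmax(p, 0), 1)
}

#' @rdname genotype_dosage
#' @param genotype Genotype string: one of `"1/1"`, `"1/2"`, `"2/2"`.
#' @export
dosage_from_genotype <- function(genotype) {
  i <- genotype_index(genotype)
  p <- c(p11 = 0, p12 = 0, p22 = 0)
  p[i] <- 1
  p
}

# genotype string -> index 1:3 (1/1, 1/2, 2/2); "2/1" accepted as 1/2
genotype_index <- function(genotype) {
  i <- match(genotype, c("1/1", "1/2", "2/2"))
  i[is.na(i) & genotype %in% "2/1"] <- 2L
  if (anyNA(i) && !all(is.na(genotype) | genotype %in% c("1/1", "1/2", "2/2", "2/1")))
    stop("unknown genotype code: ",
         paste(unique(genotype[!genotype %in% c("1/1", "1/2", "2/2", "2/1") &
                                 !is.na(genotype)]), collapse = ", "))
  i
}

GENOTYPES <- c("1/1", "1/2", "2/2")

#' Trio dosage sets
#'
#' A trio dosage set is the 3x3 table of father/mother/child genotype
#' posteriors at one marker. Sets are stored one trio per row, with the nine
#' probabilities in columns `f11, f12, f22, m11, m12, m22, c11, c12, c22`,
#' so downstream statistics can be computed with vectorized arithmetic.
#'
#' @param trio_id Trio identifier(s).
#' @param marker_id Marker identifier(s).
#' @param father,mother,child Dosage triples (see [genotype_dosage()]), or
#'   matrices with three columns (one row per trio).
#' @return A `data.frame` with one row per trio.
#' @examples
#' trio_dosage_set("t1", "rs1",
#'                 father = genotype_dosage(0, 1, 0),
#'                 mother = genotype_dosage(1, 0, 0),
#'                 child  = genotype_dosage(1, 0, 0))
#' @export
trio_dosage_set <- function(trio_id, marker_id, father, mother, child) {
  as_mat <- function(x) {
    if (is.matrix(x)) x else matrix(x, ncol = 3, byrow = TRUE)
  }
  f <- as_mat(father); m <- as_mat(mother); k <- as_mat(child)
  n <- max(nrow(f), nrow(m), nrow(k), length(trio_id))
  chk <- rbind(f, m, k)
  if (any(chk < -1e-9) || any(abs(rowSums(chk) - 1) > 1e-9))
    stop("member dosages must be non-negative and sum to 1")
  out <- data.frame(
    trio_id = rep_len(as.character(trio_id), n),
    marker_id = rep_len(as.character(marker_id), n),
    f11 = rep_len(f[, 1], n), f12 = rep_len(f[, 2], n), f22 = rep_len(f[, 3], n),
    m11 = rep_len(m[, 1], n), m12 = rep_len(m[, 2], n), m22 = rep_len(m[, 3], n),
    c11 = rep_len(k[, 1], n), c12 = rep_len(k[, 2], n), c22 = rep_len(k[, 3], n),
    stringsAsFactors = FALSE
  )
  out
}

#' Child dosage implied by parental dosages and a transmission probability
#'
#' Writes the child's genotype dosage in terms of its parents' dosages and
#' the probability `t` that a heterozygous parent transmits allele 1:
#' `p_c11 = (p_f11 + t p_f12)(p_m11 + t p_m12)`,
#' `p_c22 = (p_f22 + (1-t) p_f12)(p_m22 + (1-t) p_m12)`, and
#' `p_c12` as the complement.
#'
#' @param father,mother Dosage triples (see [genotype_dosage()]).
#' @param t Probability that a heterozygous parent transmits allele 1.
#' @return A dosage triple for the child.
#' @examples
#' child_dosage_from_parents(genotype_dosage(0, 1, 0),
#'                           genotype_dosage(0, 1, 0), t = 0.5)
#' @export
child_dosage_from_parents <- function(father, mother, t) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0 || t > 1)
    stop("t must be a probability in [0, 1]")
  p11 <- (father[1] + t * father[2]) * (mother[1] + t * mother[2])
  p22 <- (father[3] + (1 - t) * father[2]) * (mother[3] + (1 - t) * mother[2])
  genotype_dosage(unname(p11), unname(1 - p11 - p22), unname(p22))
}
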