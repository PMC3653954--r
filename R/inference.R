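#' Exact genotype posteriors for parents of one observed child
#'
#' Given an observed child genotype at a biallelic SNP and a population
#' allele-1 frequency `q1`, computes each parent's posterior genotype
#' distribution by exact enumeration of the nine parental genotype pairs
#' under a Hardy-Weinberg founder prior and Mendelian transmission. The
#' child keeps a point-mass dosage on its observed genotype.
#'
#' This is the single-marker nuclear-family analogue of the posterior
#' ("dosage") output of pedigree inference programs, suitable when no
#' flanking-marker information links the SNP to the rest of the pedigree.
#'
#' @param child_genotype One of `"1/1"`, `"1/2"`, `"2/2"`.
#' @param q1 Population frequency of allele 1, strictly inside (0, 1).
#' @param trio_id,marker_id Labels for the returned trio dosage set.
#' @return A one-row trio dosage set (see [trio_dosage_set()]).
#' @examples
#' parental_posterior("1/1", q1 = 0.5)   # each parent: (0.5, 0.5, 0)
#' @export
parental_posterior <- function(child_genotype, q1,
                               trio_id = "trio", marker_id = "marker") {
  post <- family_posterior(nuclear_family("fam", children = child_genotype,
                                          q1 = q1))
  trio_dosage_set(trio_id, marker_id,
                  father = unlist(post[post$member == "father",
                                       c("p11", "p12", "p22")]),
                  mother = unlist(post[post$member == "mother",
                                       c("p11", "p12", "p22")]),
                  child = dosage_from_genotype(child_genotype))
}

#' Nuclear-family observation
#'
#' Bundles the observed genotypes of a nuclear family at one SNP together
#' with the founder allele frequency used as the Hardy-Weinberg prior.
#'
#' @param family_id Family identifier.
#' @param children Character vector of child genotypes (`"1/1"`, `"1/2"`,
#'   `"2/2"`, or `NA` for un-genotyped children).
#' @param father,mother Observed parental genotype, or `NA` (default) when
#'   un-genotyped.
#' @param q1 Population allele-1 frequency in (0, 1).
#' @return A list of class `"nuclear_family"`.
#' @export
nuclear_family <- function(family_id, children, father = NA, mother = NA,
                           q1) {
  if (!is.numeric(q1) || length(q1) != 1 || is.na(q1) || q1 <= 0 || q1 >= 1)
    stop("q1 must lie strictly inside (0, 1)")
  if (all(is.na(children)) && is.na(father) && is.na(mother))
    stop("at least one family member must have an observed genotype")
  genotype_index(c(children, father, mother))  # validates codes
  structure(list(family_id = as.character(family_id),
                 children = as.character(children),
                 father = as.character(father), mother = as.character(mother),
                 q1 = q1),
            class = "nuclear_family")
}

# P(child index | father index, mother index): 3x3x3 Mendelian array
mendel_array <- local({
  trans <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))  # P(transmit allele 1 or 2 | geno)
  a <- array(0, c(3, 3, 3))
  for (gf in 1:3) for (gm in 1:3) {
    p11 <- trans[gf, 1] * trans[gm, 1]
    p22 <- trans[gf, 2] * trans[gm, 2]
    a[gf, gm, ] <- c(p11, 1 - p11 - p22, p22)
  }
  a
})

#' Exact posteriors for every member of a nuclear family
#'
#' Enumerates the nine parental genotype pairs with Hardy-Weinberg priors at
#' `q1`, weights each pair by the product of Mendelian transmission
#' probabilities of all observed children (children are conditionally
#' independent given the parents), and marginalizes. Observed members get
#' point masses; un-genotyped children get their posterior given the
#' parental pair distribution. With a single observed child this reduces to
#' [parental_posterior()].
#'
#' @param family A [nuclear_family()] observation.
#' @return A `data.frame` with columns `member` (`"father"`, `"mother"`,
#'   `"child1"`, ...), `observed` (genotype string or `NA`), and the
#'   posterior `p11`, `p12`, `p22`.
#' @examples
#' fam <- nuclear_family("f1", children = c("1/1", "1/1"), q1 = 0.5)
#' family_posterior(fam)
#' @export
family_posterior <- function(family) {
  stopifnot(inherits(family, "nuclear_family"))
  q1 <- family$q1
  hwe <- c(q1^2, 2 * q1 * (1 - q1), (1 - q1)^2)
  kid_idx <- genotype_index(family$children)

  # 9 parental pairs, prior restricted by any observed parent
  w <- outer(hwe, hwe)  # w[gf, gm]
  fobs <- genotype_index(family$father)
  mobs <- genotype_index(family$mother)
  if (!is.na(fobs)) w[-fobs, ] <- 0
  if (!is.na(mobs)) w[, -mobs] <- 0
  for (k in kid_idx[!is.na(kid_idx)])
    w <- w * mendel_array[, , k]
  tot <- sum(w)
  if (tot <= 0)
    stop("family ", family$family_id,
         ": observed genotypes are Mendelian-inconsistent")
  w <- w / tot

  rows <- list(
    data.frame(member = "father", observed = family$father,
               p11 = rowSums(w)[1], p12 = rowSums(w)[2], p22 = rowSums(w)[3],
               stringsAsFactors = FALSE),
    data.frame(member = "mother", observed = family$mother,
               p11 = colSums(w)[1], p12 = colSums(w)[2], p22 = colSums(w)[3],
               stringsAsFactors = FALSE)
  )
  for (j in seq_along(kid_idx)) {
    if (is.na(kid_idx[j])) {
      p <- c(sum(w * mendel_array[, , 1]), sum(w * mendel_array[, , 2]),
             sum(w * mendel_array[, , 3]))
    } else {
      p <- as.numeric(kid_idx[j] == 1:3)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(member = paste0("child", j), observed = family$children[j],
                 p11 = p[1], p12 = p[2], p22 = p[3], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Allele frequency from observed genotypes
#'
#' Counting estimator of the allele-1 frequency, clipped away from 0 and 1
#' so it can serve as a Hardy-Weinberg founder prior without degenerate
#' zero-mass genotypes.
#'
#' @param genotypes Character vector of genotypes (`NA` = missing).
#' @param eps Clipping bound (default `1e-6`).
#' @return Estimated allele-1 frequency in `[eps, 1 - eps]`.
#' @examples
#' estimate_allele_freq(c("1/1", "1/2", "2/2", "1/2"))  # 0.5
#' @export
estimate_allele_freq <- function(genotypes, eps = 1e-6) {
  i <- genotype_index(genotypes)
  i <- i[!is.na(i)]
  if (!length(i)) stop("no non-missing genotypes")
  q1 <- sum(c(2, 1, 0)[i]) / (2 * length(i))
  min(max(q1, eps), 1 - eps)
}

#' Filter a dosage table on posterior confidence
#'
#' Retains an individual's dosage at a marker only when the largest of the
#' three genotype posteriors reaches `tau`. Inference posteriors whose best
#' genotype is uncertain (max below ~0.7-0.8) carry too much noise for
#' transmission testing, so thresholding trades sample size for accuracy.
#'
#' @param dosage_table A `data.frame` with columns `individual`, `marker`,
#'   `p11`, `p12`, `p22`.
#' @param tau Retention threshold in `[0, 1]`; default 0.8.
#' @return The retained rows, with a `report` attribute: a `data.frame` of
#'   per-marker retained/dropped counts.
#' @export
apply_dosage_threshold <- function(dosage_table, tau = 0.8) {
  if (!is.numeric(tau) || length(tau) != 1 || is.na(tau) || tau < 0 || tau > 1)
    stop("tau must lie in [0, 1]")
  pmax3 <- pmax(dosage_table$p11, dosage_table$p12, dosage_table$p22)
  keep <- pmax3 >= tau
  markers <- unique(dosage_table$marker)
  report <- data.frame(
    marker = markers,
    retained = vapply(markers, function(m)
      sum(keep & dosage_table$marker == m), integer(1)),
    dropped = vapply(markers, function(m)
      sum(!keep & dosage_table$marker == m), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- dosage_table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- report
  out
}
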