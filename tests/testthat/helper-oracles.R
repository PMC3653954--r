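# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: genotype configurations are enumerated directly
# from allele counts.

GENO <- c("1/1", "1/2", "2/2")

# random dosage triple (Dirichlet-ish via normalized uniforms)
random_dosage <- function() {
  p <- stats::runif(3)
  p / sum(p)
}

# P(transmit allele 1 | genotype index)
.tr1 <- c(1, 0.5, 0)

# Brute-force nuclear-family posterior: enumerate every genotype
# configuration (father, mother, k children) over 3^(2+k) states.
brute_family_posterior <- function(children, father = NA, mother = NA, q1) {
  k <- length(children)
  hwe <- c(q1^2, 2 * q1 * (1 - q1), (1 - q1)^2)
  mendel <- function(gc, gf, gm) {
    # child genotype prob from transmitted-allele probabilities
    p1f <- .tr1[gf]; p1m <- .tr1[gm]
    c(p1f * p1m, p1f * (1 - p1m) + (1 - p1f) * p1m,
      (1 - p1f) * (1 - p1m))[gc]
  }
  states <- as.matrix(expand.grid(rep(list(1:3), 2 + k)))
  obs_idx <- function(g) if (is.na(g)) NA_integer_ else match(g, GENO)
  fo <- obs_idx(father); mo <- obs_idx(mother)
  ko <- vapply(children, obs_idx, integer(1))
  w <- apply(states, 1, function(st) {
    gf <- st[1]; gm <- st[2]
    if (!is.na(fo) && gf != fo) return(0)
    if (!is.na(mo) && gm != mo) return(0)
    p <- hwe[gf] * hwe[gm]
    for (j in seq_len(k)) {
      gc <- st[2 + j]
      if (!is.na(ko[j]) && gc != ko[j]) return(0)
      p <- p * mendel(gc, gf, gm)
    }
    p
  })
  tot <- sum(w)
  if (tot <= 0) stop("inconsistent configuration")
  w <- w / tot
  marg <- function(col) vapply(1:3, function(g) sum(w[states[, col] == g]),
                               numeric(1))
  out <- rbind(father = marg(1), mother = marg(2))
  for (j in seq_len(k)) out <- rbind(out, marg(2 + j))
  rownames(out) <- c("father", "mother", paste0("child", seq_len(k)))
  colnames(out) <- c("p11", "p12", "p22")
  out
}

# Brute-force affected-child SNP genotype distribution: sum over all
# ordered (D,S) diplotypes built from two transmitted haplotypes.
brute_affected_dist <- function(h, f11, f12, f22) {
  pen <- c(f11, f12, f22)
  hap <- expand.grid(d = 1:2, s = 1:2)      # rows: D1S1, D2S1, D1S2, D2S2
  hfreq <- c(h["h11"], h["h21"], h["h12"], h["h22"])
  acc <- c(0, 0, 0)
  for (a in 1:4) for (b in 1:4) {
    dg <- hap$d[a] + hap$d[b] - 1
    sg <- hap$s[a] + hap$s[b] - 1
    acc[sg] <- acc[sg] + hfreq[a] * hfreq[b] * pen[dg]
  }
  list(dist = acc / sum(acc), mass = sum(acc))
}

# hard-genotype trio dosage row from genotype strings
hard_trio <- function(id, gf, gm, gc, marker = "snp") {
  trio_dosage_set(id, marker,
                  father = dosage_from_genotype(gf),
                  mother = dosage_from_genotype(gm),
                  child = dosage_from_genotype(gc))
}

# enumerate classic-TDT transmission counts from hard Mendelian trios:
# each het parent contributes to b if it transmitted allele 1
count_transmissions <- function(gf, gm, gc) {
  n1 <- function(g) c(`1/1` = 2, `1/2` = 1, `2/2` = 0)[g]
  b <- 0; c_ <- 0
  # transmitted alleles: child allele-1 count split between parents;
  # resolve the one ambiguous case (both het, child het) by convention of
  # expected counts: each het parent transmits allele 1 w.p. 1/2, so both
  # configurations contribute 1 to b and 1 to c in total.
  cf <- n1(gc)
  for (split in list(c(1, 0), c(0, 1), c(1, 1), c(0, 0))) {
    # split = (allele-1 from father?, from mother?)
    if (sum(split) != cf) next
    okf <- (split[1] == 1 && n1(gf) >= 1) || (split[1] == 0 && n1(gf) <= 1)
    okm <- (split[2] == 1 && n1(gm) >= 1) || (split[2] == 0 && n1(gm) <= 1)
    if (!okf || !okm) next
    wt <- 1
    if (gf == "1/2" && gm == "1/2" && gc == "1/2") wt <- 0.5
    if (gf == "1/2") { if (split[1] == 1) b <- b + wt else c_ <- c_ + wt }
    if (gm == "1/2") { if (split[2] == 1) b <- b + wt else c_ <- c_ + wt }
  }
  c(b = unname(b), c = unname(c_))
}

# random Mendelian-consistent hard trio under allele frequency q1
random_hard_trio <- function(q1 = 0.5) {
  draw <- function() sum(stats::runif(2) < q1)  # allele-1 count
  nf <- draw(); nm <- draw()
  tf <- if (nf == 2) 1 else if (nf == 0) 0 else stats::rbinom(1, 1, 0.5)
  tm <- if (nm == 2) 1 else if (nm == 0) 0 else stats::rbinom(1, 1, 0.5)
  g <- function(n1) GENO[3 - n1]
  c(gf = g(nf), gm = g(nm), gc = g(tf + tm))
}
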