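#' Solve the risk-allele frequency implied by prevalence and penetrances
#'
#' Under Hardy-Weinberg equilibrium the population prevalence satisfies
#' `K = f11 p1^2 + 2 f12 p1 p2 + f22 p2^2` with `p2 = 1 - p1`. Collecting
#' terms gives the quadratic
#' `(f11 - 2 f12 + f22) p1^2 + 2 (f12 - f22) p1 + (f22 - K) = 0`,
#' whose root in (0, 1) is the frequency of the low-risk allele `D1`.
#'
#' Some (K, penetrance) combinations admit no root in (0, 1); those are
#' invalid model settings and are reported via `valid = FALSE` rather than
#' an error, so parameter grids can be screened. If two distinct roots fall
#' in (0, 1) (possible under the co-dominant parameterization) the larger
#' `p1` is taken — allele 2, the high-penetrance allele, stays the rarer
#' risk allele — and a message notes the choice.
#'
#' @param K Population prevalence.
#' @param f11,f12,f22 Penetrances of genotypes `D1D1`, `D1D2`, `D2D2`.
#' @return A list with `p1`, `p2` and logical `valid` (`p1`/`p2` are `NA`
#'   when invalid).
#' @examples
#' solve_risk_allele_freq(0.01, 0, 0.5, 0.5)  # dominant: p1 ~ 0.98995
#' solve_risk_allele_freq(0.01, 0, 0, 0.5)    # recessive: p2 ~ 0.14142
#' @export
solve_risk_allele_freq <- function(K, f11, f12, f22) {
  pr <- c(K = K, f11 = f11, f12 = f12, f22 = f22)
  if (anyNA(pr) || any(pr < 0) || any(pr > 1))
    stop("K and penetrances must be probabilities in [0, 1]")
  if (f11 == f12 && f12 == f22)
    stop("equal penetrances: allele frequency is not identifiable")
  a <- f11 - 2 * f12 + f22
  b <- 2 * (f12 - f22)
  cc <- f22 - K
  eps <- 1e-12
  if (abs(a) < eps) {
    roots <- if (abs(b) < eps) numeric(0) else -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    roots <- if (disc < 0) numeric(0) else
      (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
  }
  roots <- sort(unique(roots[roots > eps & roots < 1 - eps]))
  if (!length(roots))
    return(list(p1 = NA_real_, p2 = NA_real_, valid = FALSE))
  if (length(roots) > 1) {
    message("two admissible roots (",
            paste(signif(roots, 6), collapse = ", "),
            "); taking the larger p1 so allele 2 remains the rare risk allele")
  }
  p1 <- roots[length(roots)]
  resid <- f11 * p1^2 + 2 * f12 * p1 * (1 - p1) + f22 * (1 - p1)^2 - K
  stopifnot(abs(resid) < 1e-9)
  list(p1 = p1, p2 = 1 - p1, valid = TRUE)
}

#' Disease model for trio simulation
#'
#' A biallelic disease locus `D` with penetrances chosen from one of three
#' parameterizations — dominant `(f, g, g)`, recessive `(f, f, g)`, or
#' co-dominant `(f, g/2, g)` — and a SNP locus `S` in linkage
#' disequilibrium `R` with `D`. Allele frequencies at `S` are set equal to
#' those at `D` (`q = p`), which lets `R` span its full range.
#'
#' @param model `"dominant"`, `"recessive"` or `"codominant"`.
#' @param K Population prevalence.
#' @param f Penetrance of the low-risk homozygote `D1D1`.
#' @param g Penetrance of the high-risk genotype(s).
#' @param R Linkage-disequilibrium correlation between `D` and `S`, in
#'   `[0, 1]` (negative values add no information by symmetry and are
#'   excluded).
#' @return A list of class `"disease_model"` with the penetrances,
#'   `p1`/`p2` (= `q1`/`q2`), the haplotype table and the affected-child
#'   SNP genotype distribution.
#' @examples
#' disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 1)
#' @export
disease_model <- function(model = c("dominant", "recessive", "codominant"),
                          K, f, g, R) {
  model <- match.arg(model)
  pen <- switch(model,
                dominant   = c(f11 = f, f12 = g, f22 = g),
                recessive  = c(f11 = f, f12 = f, f22 = g),
                codominant = c(f11 = f, f12 = g / 2, f22 = g))
  if (!is.numeric(R) || length(R) != 1 || is.na(R) || R < 0 || R > 1)
    stop("R must lie in [0, 1]")
  root <- solve_risk_allele_freq(K, pen["f11"], pen["f12"], pen["f22"])
  if (!root$valid)
    stop("no admissible allele frequency: setting (", model, ", K=", K,
         ", f=", f, ", g=", g, ") is invalid")
  h <- haplotype_frequencies(root$p1, root$p1, R)
  dist <- affected_child_genotype_dist(h, pen["f11"], pen["f12"], pen["f22"], K)
  structure(list(model = model, K = K, f = f, g = g, R = R,
                 f11 = unname(pen["f11"]), f12 = unname(pen["f12"]),
                 f22 = unname(pen["f22"]),
                 p1 = root$p1, p2 = root$p2, q1 = root$p1, q2 = root$p2,
                 haplotypes = h, child_snp_dist = dist),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat("Disease model:", x$model, "\n",
      " K =", x$K, " penetrances =", x$f11, x$f12, x$f22, "\n",
      " p1 = q1 =", signif(x$q1, 6), " R =", x$R, "\n",
      " P(child SNP | affected) =", signif(x$child_snp_dist, 4), "\n")
  invisible(x)
}

#' Haplotype frequencies from allele frequencies and an LD coefficient
#'
#' Builds the 2x2 haplotype table of disease locus `D` and SNP locus `S`
#' from the allele frequencies and the LD correlation `R`:
#' `h11 = p1 q1 + R sqrt(p1 p2 q1 q2)` and so on, signs alternating so the
#' table has the prescribed correlation and correct margins.
#'
#' @param p1 Frequency of disease allele `D1`.
#' @param q1 Frequency of SNP allele `S1`.
#' @param R LD correlation in `[0, 1]`.
#' @return Named numeric vector `c(h11, h12, h21, h22)` (first index: D
#'   allele, second: S allele).
#' @examples
#' haplotype_frequencies(0.8, 0.8, 1)   # perfect LD: (0.8, 0, 0, 0.2)
#' @export
haplotype_frequencies <- function(p1, q1, R) {
  if (p1 <= 0 || p1 >= 1 || q1 <= 0 || q1 >= 1)
    stop("allele frequencies must lie strictly inside (0, 1)")
  if (R < 0 || R > 1) stop("R must lie in [0, 1]")
  p2 <- 1 - p1; q2 <- 1 - q1
  d <- R * sqrt(p1 * p2 * q1 * q2)
  h <- c(h11 = p1 * q1 + d, h12 = p1 * q2 - d,
         h21 = p2 * q1 - d, h22 = p2 * q2 + d)
  if (any(h < -1e-12))
    stop("R = ", R, " is incompatible with the allele frequencies ",
         "(negative haplotype frequency)")
  pmax(h, 0)
}

#' SNP genotype distribution of an affected child
#'
#' Exact enumeration over ordered pairs of parental-transmitted haplotypes:
#' each of the 4x4 pairs carries probability `h_a * h_b`, is weighted by
#' the penetrance of the implied disease-locus genotype, and is accumulated
#' by the implied SNP genotype. The unnormalized total equals the
#' prevalence `K`; dividing by it gives `P(SNP genotype | child affected)`.
#'
#' @param h Haplotype table from [haplotype_frequencies()].
#' @param f11,f12,f22 Penetrances at the disease locus.
#' @param K Prevalence (used only to cross-check the enumeration total).
#' @return Probability vector over SNP genotypes `1/1`, `1/2`, `2/2`, with
#'   the enumeration total in attribute `"prevalence"`.
#' @export
affected_child_genotype_dist <- function(h, f11, f12, f22, K = NULL) {
  pen <- c(f11, f12, f22)
  # haplotypes in order (D1S1, D1S2, D2S1, D2S2)
  d_allele <- c(1L, 1L, 2L, 2L)
  s_allele <- c(1L, 2L, 1L, 2L)
  acc <- c(0, 0, 0)
  for (a in 1:4) for (b in 1:4) {
    dg <- d_allele[a] + d_allele[b] - 1L   # 1,2,3 for D1D1, D1D2, D2D2
    sg <- s_allele[a] + s_allele[b] - 1L
    acc[sg] <- acc[sg] + h[a] * h[b] * pen[dg]
  }
  tot <- sum(acc)
  if (tot <= 0) stop("all penetrances are zero: no affected children exist")
  if (!is.null(K) && abs(tot - K) > 1e-9)
    warning("enumeration total ", format(tot),
            " differs from stated prevalence ", format(K))
  out <- unname(acc / tot)
  names(out) <- GENOTYPES
  attr(out, "prevalence") <- unname(tot)
  out
}

# run code with a private, restored RNG stream seeded at `seed`
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

# documented sub-seed splitting rule for derived streams
derive_subseed <- function(seed, k) {
  (as.numeric(seed) + 1000003 * k) %% 2147483647
}

#' Simulate a set of affected-child trios
#'
#' Draws `n` trios, each with one affected child. The child's SNP genotype
#' is sampled from the model's affected-child distribution by roulette
#' wheel (inverse CDF on the cumulative probabilities). Parents carry a
#' fully informative microsatellite — father alleles (1, 2), mother
#' alleles (3, 4) — and the child receives one of the four allele
#' combinations with probability 1/4 each. Parents carry no SNP genotype:
#' they are the "missing individuals" whose dosages are inferred
#' downstream.
#'
#' @param model A [disease_model()].
#' @param n Number of trios.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `data.frame` with one row per trio: `trio_id`, `child_snp`,
#'   microsatellite allele pairs for father/mother/child, and `affected`.
#'   Attribute `"meta"` records the model parameters, seed and RNG.
#' @examples
#' m <- disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 1)
#' head(simulate_trio_set(m, 5, seed = 1))
#' @export
simulate_trio_set <- function(model, n, seed) {
  stopifnot(inherits(model, "disease_model"), n >= 0)
  with_seed(seed, {
    if (n == 0) {
      snp <- character(0); ms <- integer(0)
    } else {
      cum <- cumsum(model$child_snp_dist)
      cum[length(cum)] <- 1  # guard the wheel against rounding in the tail
      snp <- GENOTYPES[findInterval(stats::runif(n), cum) + 1L]
      ms <- sample.int(4L, n, replace = TRUE)  # which parental combo
    }
    child_ms1 <- c(1L, 2L, 1L, 2L)[ms]  # paternal allele
    child_ms2 <- c(3L, 4L, 4L, 3L)[ms]  # maternal allele
    out <- data.frame(
      trio_id = if (n) sprintf("trio%d", seq_len(n)) else character(0),
      child_snp = snp,
      father_ms1 = rep(1L, n), father_ms2 = rep(2L, n),
      mother_ms1 = rep(3L, n), mother_ms2 = rep(4L, n),
      child_ms1 = child_ms1, child_ms2 = child_ms2,
      affected = rep(TRUE, n),
      stringsAsFactors = FALSE
    )
    attr(out, "meta") <- list(model = model$model, K = model$K, f = model$f,
                              g = model$g, R = model$R, q1 = model$q1,
                              n = n, seed = seed, rng = "Mersenne-Twister")
    out
  })
}

#' Simulate two trio strata (e.g. two subpopulations)
#'
#' Concatenates two independent trio sets simulated under different disease
#' models, with per-stratum sub-seeds derived from `seed` by the rule
#' `(seed + 1000003 k) mod (2^31 - 1)`. A `stratum` column labels
#' provenance, supporting stratification experiments in which a pooled
#' analysis can be compared with per-stratum analysis.
#'
#' @param model_a,model_b [disease_model()] objects.
#' @param n_a,n_b Trios per stratum.
#' @param seed Integer master seed.
#' @return As [simulate_trio_set()], plus a `stratum` column (`"a"`/`"b"`).
#' @export
simulate_stratified_set <- function(model_a, model_b, n_a, n_b, seed) {
  a <- simulate_trio_set(model_a, n_a, derive_subseed(seed, 1))
  b <- simulate_trio_set(model_b, n_b, derive_subseed(seed, 2))
  if (nrow(a)) a$trio_id <- paste0("a_", a$trio_id)
  if (nrow(b)) b$trio_id <- paste0("b_", b$trio_id)
  a$stratum <- rep("a", nrow(a))
  b$stratum <- rep("b", nrow(b))
  out <- rbind(a, b)
  attr(out, "meta") <- list(a = attr(a, "meta"), b = attr(b, "meta"),
                            seed = seed, rng = "Mersenne-Twister",
                            subseed_rule = "(seed + 1000003*k) mod 2^31-1")
  out
}

#' Evaluation grid of disease-model settings
#'
#' The full Cartesian grid per (model, prevalence) group:
#' `R` in \{0.5, 0.7, 0.9, 1.0\}, low penetrance
#' `f` in \{0, 0.1K, 0.3K, 0.5K, 0.7K, 0.9K\}, high penetrance
#' `g` in \{1.1K, 0.5, 0.7, 0.9, 1.0\} — 120 raw settings per group, with
#' models dominant/recessive/codominant and `K` in \{0.01, 0.1, 0.2\}.
#' Settings for which no allele frequency in (0, 1) satisfies the
#' prevalence identity are flagged invalid and excluded from analysis.
#'
#' @return A `data.frame` with one row per raw setting: `model`, `K`, `R`,
#'   `f`, `g`, the implied penetrances, `valid` and `p1` (`NA` if invalid).
#' @export
parameter_grid <- function() {
  grid <- expand.grid(
    model = c("dominant", "recessive", "codominant"),
    K = c(0.01, 0.1, 0.2),
    R = c(0.5, 0.7, 0.9, 1.0),
    f_mult = c(0, 0.1, 0.3, 0.5, 0.7, 0.9),
    g_code = 1:5,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$f <- grid$f_mult * grid$K
  grid$g <- ifelse(grid$g_code == 1, 1.1 * grid$K,
                   c(NA, 0.5, 0.7, 0.9, 1.0)[grid$g_code])
  grid$f_mult <- grid$g_code <- NULL
  pen <- t(mapply(function(model, f, g) {
    switch(model,
           dominant   = c(f, g, g),
           recessive  = c(f, f, g),
           codominant = c(f, g / 2, g))
  }, grid$model, grid$f, grid$g))
  grid$f11 <- pen[, 1]; grid$f12 <- pen[, 2]; grid$f22 <- pen[, 3]
  sol <- suppressMessages(
    mapply(function(K, f11, f12, f22) {
      if (f11 == f12 && f12 == f22)
        return(c(NA_real_, FALSE))
      r <- solve_risk_allele_freq(K, f11, f12, f22)
      c(r$p1, r$valid)
    }, grid$K, grid$f11, grid$f12, grid$f22)
  )
  grid$p1 <- sol[1, ]
  grid$valid <- as.logical(sol[2, ])
  grid[order(grid$model, grid$K, grid$R, -grid$f, grid$g), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}
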