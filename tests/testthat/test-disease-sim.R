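test_that("risk-allele frequency solves the prevalence identity", {
  # dominant f=0, g=0.5, K=0.01: closed-form sqrt((g-K)/g)
  r <- solve_risk_allele_freq(0.01, 0, 0.5, 0.5)
  expect_true(r$valid)
  expect_equal(r$p1, sqrt(0.49 / 0.5), tolerance = 1e-9)
  # recessive: p2 = sqrt(K/g)
  r <- solve_risk_allele_freq(0.01, 0, 0, 0.5)
  expect_equal(r$p2, sqrt(0.02), tolerance = 1e-9)
  expect_equal(r$p1, 1 - sqrt(0.02), tolerance = 1e-9)
  # residual check across random valid settings
  set.seed(2)
  for (i in 1:40) {
    f <- runif(1, 0, 0.1); g <- runif(1, 0.3, 1); K <- runif(1, 0.05, 0.25)
    r <- solve_risk_allele_freq(K, f, f, g)
    if (!r$valid) next
    resid <- f * r$p1^2 + 2 * f * r$p1 * r$p2 + g * r$p2^2 - K
    expect_lt(abs(resid), 1e-9)
  }
  expect_error(solve_risk_allele_freq(0.1, 0.1, 0.1, 0.1),
               "not identifiable")
  # no admissible root: prevalence above every penetrance
  expect_false(solve_risk_allele_freq(0.9, 0.1, 0.1, 0.2)$valid)
})

test_that("haplotype table has correct margins, LD limits and positivity", {
  h <- haplotype_frequencies(0.3, 0.6, 0)
  expect_equal(unname(h["h11"]), 0.3 * 0.6)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  # perfect LD with equal frequencies collapses to the two coupled haplotypes
  h <- haplotype_frequencies(0.8, 0.8, 1)
  expect_equal(unname(h), c(0.8, 0, 0, 0.2), tolerance = 1e-12)
  # derived frequency from the closed form
  p1 <- 1 - sqrt(0.02)
  h <- haplotype_frequencies(p1, p1, 0.7)
  expect_equal(unname(h["h11"]), p1^2 + 0.7 * p1 * (1 - p1),
               tolerance = 1e-9)
  expect_error(haplotype_frequencies(0.1, 0.9, 1), "negative haplotype")
})

test_that("affected-child genotype distribution matches exact enumeration", {
  # R = 1, p = q: SNP and disease locus coincide
  r <- solve_risk_allele_freq(0.01, 0, 0, 0.5)
  h <- haplotype_frequencies(r$p1, r$p1, 1)
  d <- affected_child_genotype_dist(h, 0, 0, 0.5, K = 0.01)
  expect_equal(unname(d[1]), r$p1^2 * 0 / 0.01)
  expect_equal(unname(d[3]), r$p2^2 * 0.5 / 0.01, tolerance = 1e-9)
  # R = 0: independence, HWE at q1 regardless of penetrances
  h <- haplotype_frequencies(r$p1, r$p1, 0)
  d <- affected_child_genotype_dist(h, 0, 0, 0.5, K = 0.01)
  expect_equal(as.numeric(d), c(r$p1^2, 2 * r$p1 * r$p2, r$p2^2),
               tolerance = 1e-12)
  # intermediate LD: brute-force diplotype oracle
  h <- haplotype_frequencies(r$p1, r$p1, 0.7)
  d <- affected_child_genotype_dist(h, 0, 0, 0.5, K = 0.01)
  ref <- brute_affected_dist(h, 0, 0, 0.5)
  expect_equal(as.numeric(d), ref$dist, tolerance = 1e-12)
  expect_equal(attr(d, "prevalence"), 0.01, tolerance = 1e-9)
  expect_error(affected_child_genotype_dist(h, 0, 0, 0), "penetrances")
})

test_that("prevalence identity holds across every valid grid setting", {
  grid <- parameter_grid()
  valid <- grid[grid$valid, ]
  for (i in seq_len(nrow(valid))) {
    s <- valid[i, ]
    h <- haplotype_frequencies(s$p1, s$p1, s$R)
    expect_true(all(h >= 0))
    expect_equal(sum(h), 1, tolerance = 1e-9)
    d <- affected_child_genotype_dist(h, s$f11, s$f12, s$f22, K = s$K)
    expect_equal(attr(d, "prevalence"), s$K, tolerance = 1e-9)
  }
})

test_that("the parameter grid has 120 raw settings per (model, K) group", {
  grid <- parameter_grid()
  counts <- table(grid$model, grid$K)
  expect_true(all(counts == 120))
  surv <- tapply(grid$valid, paste(grid$model, grid$K), sum)
  expect_true(all(surv >= 100 & surv <= 120))
  # surviving settings round-trip the prevalence identity
  v <- grid[grid$valid, ]
  resid <- v$f11 * v$p1^2 + 2 * v$f12 * v$p1 * (1 - v$p1) +
    v$f22 * (1 - v$p1)^2 - v$K
  expect_lt(max(abs(resid)), 1e-9)
})

test_that("trio simulation is deterministic and matches the analytic law", {
  m <- disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 1)
  expect_equal(simulate_trio_set(m, 0, seed = 1),
               simulate_trio_set(m, 0, seed = 2), ignore_attr = TRUE)
  a <- simulate_trio_set(m, 200, seed = 9)
  b <- simulate_trio_set(m, 200, seed = 9)
  expect_identical(a, b)
  # microsatellite structure: fully informative parents, child inherits
  expect_true(all(a$father_ms1 == 1 & a$father_ms2 == 2))
  expect_true(all(a$child_ms1 %in% 1:2 & a$child_ms2 %in% 3:4))
  # empirical genotype frequencies within 3 binomial SEs of the law
  m2 <- disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 0.7)
  big <- simulate_trio_set(m2, 10000, seed = 4)
  emp <- table(factor(big$child_snp, GENO)) / 10000
  for (g in 1:3) {
    p <- m2$child_snp_dist[g]
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(emp[g] - p), 3 * se + 1e-12)
  }
})

test_that("stratified simulation concatenates labelled independent strata", {
  ma <- disease_model("dominant", K = 0.1, f = 0, g = 0.5, R = 0.5)
  mb <- disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 0.9)
  s <- simulate_stratified_set(ma, mb, 30, 20, seed = 5)
  expect_equal(nrow(s), 50)
  expect_equal(sum(s$stratum == "a"), 30)
  expect_equal(sum(s$stratum == "b"), 20)
  # n_b = 0 reduces to a single-model simulation
  s0 <- simulate_stratified_set(ma, mb, 30, 0, seed = 5)
  expect_equal(s0$child_snp, s$child_snp[s$stratum == "a"])
})

test_that("transmissions are centered under the null (R = 0)", {
  m <- disease_model("dominant", K = 0.1, f = 0, g = 0.5, R = 0)
  diffs <- vapply(1:500, function(r) {
    trios <- simulate_trio_set(m, 200, seed = 20000 + r)
    res <- dtdt_run(trios, m$q1)
    res$sum_b - res$sum_c
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se)
})
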