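test_that("child dosage follows from parental dosages and t", {
  # homozygous parents force the child genotype regardless of t
  for (t in c(0, 0.3, 1)) {
    expect_equal(unname(child_dosage_from_parents(
      genotype_dosage(1, 0, 0), genotype_dosage(1, 0, 0), t)), c(1, 0, 0))
  }
  # two heterozygotes at t = 0.5 give Mendelian 1:2:1
  expect_equal(unname(child_dosage_from_parents(
    genotype_dosage(0, 1, 0), genotype_dosage(0, 1, 0), 0.5)),
    c(0.25, 0.5, 0.25))
  # general dosages: direct evaluation of the product form
  got <- child_dosage_from_parents(genotype_dosage(0.2, 0.5, 0.3),
                                   genotype_dosage(0.1, 0.6, 0.3), 0.7)
  expect_equal(unname(got), c(0.286, 0.498, 0.216), tolerance = 1e-12)
  expect_error(child_dosage_from_parents(genotype_dosage(1, 0, 0),
                                         genotype_dosage(1, 0, 0), 1.2),
               "t must be")
})

test_that("trio increments compute b, c with conservation b + c = s", {
  # hard genotypes: het father transmitting allele 1
  tr <- hard_trio("t1", "1/2", "1/1", "1/1")
  inc <- trio_increments(tr)
  expect_equal(inc$b, 1)
  expect_equal(inc$c, 0)
  # dosage trio built forward at t = 0.7: b = s * t
  f <- genotype_dosage(0.2, 0.5, 0.3)
  m <- genotype_dosage(0.1, 0.6, 0.3)
  tr <- trio_dosage_set("t2", "rs1", f, m,
                        child_dosage_from_parents(f, m, 0.7))
  inc <- trio_increments(tr)
  expect_equal(inc$b, 1.1 * 0.7, tolerance = 1e-12)
  expect_equal(inc$c, 1.1 * 0.3, tolerance = 1e-12)
  # conservation holds for random dosages (pre- and post-clamp)
  set.seed(42)
  for (i in 1:50) {
    tr <- trio_dosage_set("t", "rs", random_dosage(), random_dosage(),
                          random_dosage())
    inc <- suppressWarnings(trio_increments(tr))
    expect_equal(inc$b + inc$c, tr$f12 + tr$m12, tolerance = 1e-9)
    expect_gte(inc$b, 0)
    expect_gte(inc$c, 0)
  }
})

test_that("Mendelian-inconsistent dosages are clamped, not propagated", {
  tr <- hard_trio("bad", "1/1", "1/2", "2/2")  # impossible: child 2/2
  expect_warning(inc <- trio_increments(tr), "clamped")
  expect_equal(inc$b, 0)
  expect_equal(inc$c, 1)
  expect_true(inc$clamped)
  # raw values recoverable for diagnostics
  raw <- trio_increments(tr, clamp = FALSE)
  expect_equal(raw$b, -1)
  expect_false(raw$clamped)
})

test_that("uninformative trios (both parents homozygous) contribute zero", {
  tr <- hard_trio("t", "1/1", "2/2", "1/2")
  inc <- trio_increments(tr)
  expect_equal(inc$b, 0)
  expect_equal(inc$c, 0)
  res <- dtdt_statistic(inc)
  expect_equal(res$chi2, 0)
  expect_equal(res$p_value, 1)
  expect_true(is.na(res$t_hat))
  expect_equal(res$n_informative, 0)
})

test_that("pooled dTDT statistic matches the closed form and 1-df tail", {
  inc <- data.frame(trio_id = c("a", "b"), marker_id = "rs",
                    b = c(10, 5), c = c(2, 3), s = c(12, 8),
                    clamped = FALSE)
  res <- dtdt_statistic(inc)
  expect_equal(res$sum_b, 15)
  expect_equal(res$sum_c, 5)
  expect_equal(res$chi2, 5)
  expect_equal(res$p_value, pchisq(5, 1, lower.tail = FALSE))
  expect_equal(res$t_hat, 0.75)
  # balanced transmissions: no signal
  bal <- dtdt_statistic(data.frame(trio_id = "a", marker_id = "rs",
                                   b = 10, c = 10, s = 20, clamped = FALSE))
  expect_equal(bal$chi2, 0)
  expect_equal(bal$p_value, 1)
})

test_that("classic TDT validates counts and matches (b-c)^2/(b+c)", {
  expect_equal(classic_tdt(15, 5)$chi2, 5)
  expect_equal(classic_tdt(7, 7)$p_value, 1)
  expect_equal(classic_tdt(0, 0)$chi2, 0)
  expect_equal(classic_tdt(0, 0)$p_value, 1)
  expect_error(classic_tdt(-1, 2), "non-negative")
  expect_error(classic_tdt(1.5, 2), "non-negative integer")
})

test_that("dTDT reduces to the classic TDT on hard Mendelian trios", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(1:60, 1)
    trios <- t(replicate(n, random_hard_trio(q1 = runif(1, 0.2, 0.8))))
    set <- do.call(rbind, lapply(seq_len(n), function(i)
      hard_trio(paste0("t", i), trios[i, 1], trios[i, 2], trios[i, 3])))
    counts <- rowSums(vapply(seq_len(n), function(i)
      count_transmissions(trios[i, 1], trios[i, 2], trios[i, 3]),
      numeric(2)))
    got <- dtdt_statistic(trio_increments(set))
    expect_equal(got$sum_b, unname(counts["b"]), tolerance = 1e-12)
    expect_equal(got$sum_c, unname(counts["c"]), tolerance = 1e-12)
    if (counts["b"] + counts["c"] > 0) {
      ref <- (counts["b"] - counts["c"])^2 / (counts["b"] + counts["c"])
      expect_equal(got$chi2, unname(ref), tolerance = 1e-12)
    }
  }
})

test_that("t is recovered from a forward-built child dosage", {
  set.seed(11)
  for (i in 1:100) {
    f <- random_dosage(); m <- random_dosage()
    if (f[2] + m[2] <= 1e-6) next
    t <- runif(1)
    tr <- trio_dosage_set("t", "rs", f, m, child_dosage_from_parents(f, m, t))
    res <- dtdt_statistic(trio_increments(tr))
    expect_equal(res$t_hat, t, tolerance = 1e-9)
  }
})

test_that("statistic is invariant to trio order and father/mother swap", {
  set.seed(3)
  trios <- do.call(rbind, lapply(1:30, function(i)
    trio_dosage_set(paste0("t", i), "rs", random_dosage(), random_dosage(),
                    random_dosage())))
  base <- suppressWarnings(dtdt_statistic(trio_increments(trios)))
  perm <- trios[sample(nrow(trios)), ]
  swapped <- trios
  swapped[, c("f11", "f12", "f22")] <- trios[, c("m11", "m12", "m22")]
  swapped[, c("m11", "m12", "m22")] <- trios[, c("f11", "f12", "f22")]
  for (variant in list(perm, swapped)) {
    got <- suppressWarnings(dtdt_statistic(trio_increments(variant)))
    expect_equal(got$chi2, base$chi2, tolerance = 1e-12)
    expect_equal(got$sum_b, base$sum_b, tolerance = 1e-12)
  }
})
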