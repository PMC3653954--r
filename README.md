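# dtdt — dosage Transmission/Disequilibrium Test

Family-based association testing for parent–child trios in which some
members have no hard genotype calls, only posterior genotype
probabilities ("dosages") produced by pedigree inference or imputation.
Typical users are statistical geneticists holding legacy linkage
collections — families microsatellite-genotyped decades ago — who want to
reuse them for SNP association without re-genotyping every member.

## The statistic

For a biallelic SNP with alleles 1 and 2, let `t` be the probability that
a heterozygous parent transmits allele 1 to an affected child
(`t = 1/2` under no association). From the nine dosages of a trio
(father, mother, child × genotypes 1/1, 1/2, 2/2), the expected
transmission pseudo-counts are

    b_i = 2 p_c11 + p_c12 − p_f11 − p_m11        (allele-1 transmissions)
    c_i = (p_f12 + p_m12) − b_i                  (allele-2 transmissions)

which always satisfy `b_i + c_i = p_f12 + p_m12`, the trio's
heterozygosity mass. Pooled over trios,

    χ² = (Σb − Σc)² / (Σb + Σc)   ~   χ²₁  under the null,

with `t̂ = Σb / (Σb + Σc)`. When every dosage is 0 or 1 this is exactly
the classic TDT. The package also provides:

* **exact parental posteriors** for nuclear families (Hardy–Weinberg
  founder prior × Mendelian transmission, enumerated exactly), plus an
  allele-frequency estimator and a dosage-confidence filter;
* a **trio simulator** under dominant/recessive/co-dominant disease
  models parameterized by prevalence `K`, penetrances and LD correlation
  `R` between disease locus and SNP, with the standard evaluation grid;
* the **case-control allele test** in hypergeometric (O, E, Var) form and
  its **Mantel–Haenszel combination** with the dTDT,
  `χ²_MH = (Σ(O−E))² / ΣVar`;
* **common-map utilities** (SNP genetic positions interpolated from
  microsatellite anchors; MAF/flank marker cleaning) and readers/writers
  for LINKAGE/MERLIN-style ped/dat/map, dosage and results files.

## Worked example

Simulate 1,000 affected-child trios under a rare recessive model in
strong LD with the tested SNP, infer the un-genotyped parents' dosages,
and test:

```r
library(dtdt)
m <- disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 0.9)
trios <- simulate_trio_set(m, n = 1000, seed = 1)
dtdt_run(trios, q1 = m$q1)
#>   marker_id sum_b sum_c   t_hat chi2    p_value neglog10_p n_trios n_informative
#> 1       snp 23.48  1575 0.01469 1506 2.225e-308      328.6    1000          1000
```

Allele 2 (the recessive risk allele, population frequency 0.14) is
transmitted almost exclusively: of ~1,598 expected heterozygous-parent
transmissions, only 23.5 carry allele 1 (`t̂ ≈ 0.015` versus the null
0.5), giving an overwhelming χ² — the configuration in which transmission
tests are most powerful. Combining a dTDT result with an independent
case-control sample at the same SNP:

```r
mantel_haenszel_combine(list(
  case_control_allele_test(10, 5, 5, 10),   # allele counts cases/controls
  dtdt_stratum_stats(15, 5)))               # pooled Σb, Σc
#> $chi2      8.108
#> $p_value   0.004407
#> $direction 1
```

Both strata point the same way (allele 1 over-represented), so the pooled
χ² exceeds either component's.

A command-line wrapper is installed at `exec/dtdt` with subcommands
`simulate`, `infer`, `dtdt`, `cc`, `mh` and `map`; run it with `Rscript`
against file-based inputs (see the header of that script for usage).

See `vignettes/dosage-tdt-methods.Rmd` for the model, the simulator's
assumptions, and the design decisions.

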