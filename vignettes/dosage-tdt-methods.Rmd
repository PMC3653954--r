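---
title: "The dosage TDT: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dosage TDT: model, simulator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtdt)
```

## The problem

The Transmission/Disequilibrium Test (TDT) asks whether heterozygous
parents transmit one allele of a biallelic marker to their affected
children more often than the Mendelian 50:50 expectation. Because the
non-transmitted alleles act as internal controls, the test is robust to
population stratification — but it requires *complete* genotypes for both
parents and the child, which family collections rarely provide. When
parents were genotyped only on sparse linkage markers (microsatellites)
while dense SNPs were typed in a subset of offspring, pedigree inference
programs can produce, for each un-genotyped individual and SNP, a
posterior probability triple over the three genotypes — a *dosage*. The
classic TDT cannot consume dosages; this package implements the test that
can.

## The dosage TDT

Code alleles 1 and 2, and let `t` be the probability that a heterozygous
parent of an affected child transmits allele 1 (`t = 1/2` under the
null). Writing `p_f = (p_f11, p_f12, p_f22)` for the father's dosage (and
similarly for mother and child), the child's dosage implied by the
parents is

```
p_c11 = (p_f11 + t p_f12)(p_m11 + t p_m12)
p_c22 = (p_f22 + (1-t) p_f12)(p_m22 + (1-t) p_m12)
p_c12 = 1 - p_c11 - p_c22.
```

Summing the eleven transmission configurations in which at least one
parent is heterozygous gives the expected transmission pseudo-counts of
trio `i`:

```
b_i = (p_f12 + p_m12) t        (allele 1)
c_i = (p_f12 + p_m12) (1 - t)  (allele 2),
```

and eliminating `t` yields the closed form actually computed,

```
b_i = 2 p_c11 + p_c12 - p_f11 - p_m11,      c_i = (p_f12 + p_m12) - b_i,
```

which needs only the nine observed dosages. Pooling over trios,

```
chi2 = (sum b_i - sum c_i)^2 / (sum b_i + sum c_i)  ~  chi-square, 1 df,
```

with `t` estimated by `sum b / (sum b + sum c)`. When every dosage is 0
or 1 and the trio is Mendelian-consistent, `b_i` and `c_i` are the
classic transmission counts and the statistic reduces *exactly* to the
original TDT; the test suite asserts this reduction to `1e-12` on
randomly generated complete trios.

```{r}
f <- genotype_dosage(0.2, 0.5, 0.3)
m <- genotype_dosage(0.1, 0.6, 0.3)
tr <- trio_dosage_set("t1", "rs1", f, m,
                      child_dosage_from_parents(f, m, t = 0.7))
trio_increments(tr)         # b = 1.1 * 0.7, c = 1.1 * 0.3
dtdt_statistic(trio_increments(tr))
```

### Numerical choices

* **Conservation.** `b_i + c_i = p_f12 + p_m12` holds algebraically; the
  implementation preserves it through clamping too.
* **Clamping.** Dosage sets inconsistent with any `t` in [0, 1] (possible
  with miscalled hard genotypes, never with coherent posteriors) would
  produce negative pseudo-counts and break the chi-square contract. Raw
  `b_i` outside `[0, s_i]` by more than `1e-9` is clamped to the boundary
  with a warning and a per-trio flag; overshoot within `1e-9` is treated
  as round-off and clipped silently. `clamp = FALSE` exposes raw values
  for diagnostics.
* **Uninformative trios** (`p_f12 + p_m12 = 0`) contribute nothing but
  stay in `n_trios`, mirroring the classic test's treatment of two
  homozygous parents.
* **Underflow.** Strong simulated signals push the 1-df upper tail below
  the smallest representable double. `p_value` is floored at
  `.Machine$double.xmin` (the invariant `p > 0` holds), and
  `neglog10_p` is computed from `pchisq(..., log.p = TRUE)`, which is
  exact at any magnitude; power summaries use it.
* **Out-of-range `t_hat`** cannot arise after clamping since
  `0 <= sum b <= sum(b + c)`; with zero informative mass `t_hat` is `NA`
  and `p = 1`.

## Parental inference for nuclear families

`family_posterior()` computes exact genotype posteriors by enumerating
the nine parental genotype pairs under a Hardy-Weinberg prior at a founder
allele frequency `q1`, weighting by the product of Mendelian transmission
probabilities of the observed children (conditionally independent given
the parents), and marginalizing. This is a single-marker computation: it
deliberately ignores flanking markers and recombination, which is the
correct reduction when the linked marker is fully informative and no
recombination parameter links it to the SNP — the situation the simulator
constructs. Posteriors from real multipoint inference programs can be
substituted through the dosage-table reader; the two sources are
interchangeable downstream.

The founder prior defaults to the frequency estimated from all observed
genotypes at the marker (`estimate_allele_freq()`, clipped to
`[1e-6, 1 - 1e-6]` to avoid degenerate priors), and can be overridden
with an external estimate. For simulated data the pipeline passes the
model's population frequency: estimating it from affected children alone
would bias the prior toward the risk allele and distort the test.

A confidence filter (`apply_dosage_threshold()`, default `tau = 0.8`)
retains a dosage only when its largest component reaches `tau`; posteriors
below that level carry too much inference noise to be worth testing, at
the cost of sample size.

## The trio simulator

The simulator defines the study conditions under which the package's
operating characteristics are measured. A disease locus `D` has alleles
`D1` (low risk, frequency `p1`) and `D2`; penetrances follow one of three
parameterizations — dominant `(f, g, g)`, recessive `(f, f, g)`,
co-dominant `(f, g/2, g)` — and the prevalence identity
`K = f11 p1^2 + 2 f12 p1 p2 + f22 p2^2` fixes `p1` as the root in (0, 1)
of a quadratic (`solve_risk_allele_freq()`). Settings with no admissible
root are flagged invalid and excluded. Within the evaluation grid the
root in (0, 1) is always unique (the quadratic changes sign across the
interval because `f < K < g` by construction); if a co-dominant setting
outside the grid ever admits two roots, the larger `p1` is taken so that
allele 2 remains the rarer risk allele, with a message.

The tested SNP `S` has allele frequencies equal to the disease locus
(`q = p`) — with unequal frequencies the attainable LD correlation `R`
shrinks and power questions conflate two effects — and haplotype
frequencies `h11 = p1 q1 + R sqrt(p1 p2 q1 q2)` etc. Negative `R` is
excluded by contract (symmetry adds no information). An affected child's
SNP genotype distribution follows from exact enumeration of the 16
ordered haplotype pairs weighted by penetrance; the unnormalized total
equals `K`, an identity the test suite checks across every grid setting.
Children are assigned genotypes by roulette wheel on the cumulative
distribution. Each parent is heterozygous at a microsatellite with four
distinct alleles (father 1/2, mother 3/4), the child inheriting one of
the four combinations uniformly; the microsatellite is generated
independently of the SNP because no recombination parameter is modeled —
its role is to make parents "linkage-genotyped" for trio extraction.

Defaults follow the evaluation design: 1,000 trios per set;
`K` in {0.01, 0.1, 0.2}; `R` in {0.5, 0.7, 0.9, 1.0}; `f` in
{0, 0.1K, ..., 0.9K}; `g` in {1.1K, 0.5, 0.7, 0.9, 1.0}; 120 raw settings
per (model, K) group. All randomness is Mersenne-Twister under a caller
seed, with sub-streams derived by the documented rule
`(seed + 1000003 k) mod (2^31 - 1)`; simulation output carries a metadata
attribute echoing parameters, seed and generator.

What the simulator does *not* emulate: genotyping error, missingness
patterns, multipoint inference noise, extended pedigrees, ascertainment
beyond one affected child per trio, and population admixture within a
stratum. Passing tests therefore demonstrate correctness of the
statistics and calibration under the stated generative model, not
robustness to artifacts of real data — the dosage-threshold filter and
the stratified simulator (`simulate_stratified_set()`) exist to probe
the latter.

### Problem sizes

The shipped checks use 1,000 replicates of 500 complete trios for null
calibration, and 200 replicates of 1,000 trios per LD value for the
power comparison (recessive `K = 0.01` across `R`, against dominant
`K = 0.2` at `R = 1`), sizes at which the binomial error of a rejection
rate and the replicate spread of a median are small relative to the
effects being demonstrated.

```{r}
m <- disease_model("recessive", K = 0.01, f = 0, g = 0.5, R = 0.9)
trios <- simulate_trio_set(m, n = 1000, seed = 1)
dtdt_run(trios, q1 = m$q1)
```

## Case-control combination

An independent case-control sample tests the same SNP through the 2x2
allele-count table. Both tests are expressed as observed/expected/
variance triples so a Mantel-Haenszel combination can pool them:

| | case-control | dTDT |
|---|---|---|
| O | allele-1 count in cases | `sum b` |
| E | margin product / N | `(b + c)/2` |
| Var | `r1 r2 c1 c2 / (N^2 (N-1))` | `(b + c)/4` |

and `chi2_MH = (sum (O - E))^2 / sum Var`, 1 df. The case-control
variance is the hypergeometric form, equal to the Pearson chi-square
scaled by `(N-1)/N` — an identity the suite verifies on random tables.
No continuity correction is applied anywhere. Markers with a zero margin
are reported as undefined and skipped, not patched with pseudo-counts.
Two caveats the diagnostics surface: strata with opposite effect
directions cancel in MH pooling, and because both component tests depend
on population allele frequencies, their combination *double-counts*
stratification — QQ coordinates (`qq_coordinates()`, plotting positions
`(i - 0.5)/n`) are provided to check inflation.

```{r}
mantel_haenszel_combine(list(
  case_control_allele_test(10, 5, 5, 10),
  dtdt_stratum_stats(15, 5)))
```

## Genetic map construction

SNPs are placed on the microsatellite genetic map by linear interpolation
of genetic position against physical position between flanking anchors,
falling back to the 1 cM per Mb convention beyond a chromosome's first or
last anchor. Cleaning precedes mapping: microsatellites without physical
positions are dropped, then SNPs with MAF at or below 0.05 (boundary
inclusive), then SNPs within 1,000 bp (inclusive) of any *retained*
microsatellite — the flank rule uses post-cleaning anchors, and the
fixed rule order makes exclusion reports reproducible. Anchors sharing a
genetic position define a zero-length genetic interval; SNPs between them
map to the shared value. Interpolated position is non-decreasing in
physical position whenever the anchors are valid, and cleaning is
idempotent.

## Known limitations

* Biallelic SNPs only; the multi-allelic TDT family (sib-TDT, PDT, FBAT)
  is out of scope.
* The exact parental posterior is single-marker; it is a stand-in for —
  not a replacement of — multipoint pedigree inference on deep pedigrees.
* The Mantel-Haenszel combination inherits (and compounds) the component
  tests' sensitivity to population stratification; it should be read
  alongside its QQ diagnostic, and per-stratum analysis is preferable
  when strata are identifiable.
* Simulated trios condition on one affected child; parental phenotypes
  are never used.
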