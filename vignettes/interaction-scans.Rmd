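---
title: "Scanning for SNP-SNP interactions on quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for SNP-SNP interactions on quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(epihub)
library(dplyr)
```

## The model and the test

epihub tests whether two biallelic SNPs interact in their effect on a
continuous trait — high-density lipoprotein cholesterol (HDL-C, mg/dl) is the
motivating example — beyond anything either SNP does on its own. For each
pair it fits two nested linear models on complete cases:

* **marginal**: `Y = Z β0 + a1 x1 + d1 z1 + a2 x2 + d2 z2 + ε`
* **full**: the marginal model plus the four products
  `i_aa x1 x2 + i_ad x1 z2 + i_da z1 x2 + i_dd z1 z2`

Here `Z` holds the intercept and covariates (age in years, sex coded 0/1,
BMI in kg/m²), `x_i` is the minor-allele dosage (0/1/2) of SNP `i`, `z_i`
its heterozygote indicator, `a`/`d` are additive and dominance effects, and
the four `i` terms are the additive-by-additive through
dominance-by-dominance interactions. The models are compared with an F-test:

```
F = [(RSS_marginal - RSS_full) / q] / [RSS_full / (n - rank_full)]
```

with `q = rank_full - rank_marginal`, which is 4 when all nine genotype
combinations occur. Because the marginal model is nested in the full one,
this is a test for *pure* interaction: any main effect, however strong, is
absorbed by the marginal terms. The difference in R² between the two models
(`delta_r2`) is the fraction of trait variance attributable to the
interaction alone; `delta_r2_vs_single` reports the full model's R² gain
over the covariates-plus-anchor-SNP model, the variant used when one SNP is
the designated hub anchor.

Assumptions worth keeping in mind: the trait is conditionally Gaussian with
homoscedastic errors; samples are unrelated (no mixed-model relatedness
correction); covariate effects are linear. The F-test is exact under these
assumptions, which is what the calibration tests verify.

### Genotype coding is cosmetic

`encode_genotype()` offers the 0/1/2 + 0/1/0 coding (default, interpretable
as allele dosage and heterozygosity) and a centered alternative
(x in −1/0/1, z in ±0.5). Both span the same column space over the three
genotype classes, so F, p and both R² values are identical to numerical
precision under either choice; a property test enforces agreement to 1e-10.

### Degenerate pairs

When a genotype class is absent, the interaction space can have rank below
4; the test then uses the realized rank difference `q` rather than forcing
4 degrees of freedom. When the interaction columns add no rank at all
(`q = 0` — for example two rare binary variants with disjoint carriers) the
pair is flagged *untestable* and excluded from the multiplicity count: it
produces no P value, and pretending `p = 1` would distort Benjamini-Hochberg
corrections. SNPs monomorphic on the complete-case subset are likewise
flagged. P values are capped at 1; zero P values in QQ exports are clamped
to the smallest positive double and flagged.

## The scan pipeline

A typical candidate-panel analysis chains:

```{r, eval = FALSE}
g   <- read_plink_bed("cohort.bed")
ct  <- read_cohort_table("cohort.pheno", "cohort.covar")
qc  <- apply_qc(g)                 # samples < 90% call rate, SNPs < 90%, HWE P < 0.001
sc  <- all_pairs_scan(qc$genotypes, ct, min_cell = 10, fdr_q = 0.25)
write_results(sc, "scan.tsv")
autoplot(sc)                       # QQ diagnostic
```

Decisions embedded in that chain:

* **QC order** is fixed: low-call-rate samples first, then SNP call rate and
  the Hardy-Weinberg exact test computed on the retained samples only.
  Thresholds are strict inequalities (a sample at exactly 90% is kept). The
  HWE test is the conditional exact test with probability-mass ordering;
  a chi-square variant (`hwe_chisq_test()`) is exposed for very large counts.
* **Pair filter**: a pair is tested only if the rarest of its nine genotype
  combinations is carried by at least `min_cell = 10` individuals
  (inclusive boundary; an empty cell always fails). This keeps the F-test's
  cell-mean estimates anchored on real data and controls false positives
  from near-empty cells.
* **Multiplicity**: Bonferroni corrects for the number of pairs actually
  *tested* (post-filter, testable), not pairs enumerated — untestable and
  filtered pairs produce no P value. Benjamini-Hochberg q-values are
  computed over the same set; the hub scan's default discovery threshold is
  q ≤ 0.25, a deliberately permissive screen for follow-up rather than a
  confirmatory level.
* **Missing genotypes** are handled per pair by complete-case restriction,
  the only option consistent with single-pass linear fits; the trait and
  covariates are complete-cased once per scan.

`hub_scan()` runs the same machinery for one anchor SNP against every
partner in a (typically LD-pruned) panel. Partners within 1 Mb of the anchor
are flagged `near_anchor` but not excluded — proximity in LD with the anchor
can masquerade as interaction, and the flag lets the analyst decide.

### LD pruning

`ld_prune()` implements `--indep-pairwise WINDOW STEP R2` semantics: within
each window of 50 consecutive retained SNPs (per chromosome), while any pair
exceeds r² = 0.5 the member with the lower call rate (ties: later position)
is removed; the window slides by 5. Sweeps repeat until a full pass removes
nothing, so the post-condition — no kept pair within any window placement
above the ceiling — holds by construction and is verified exhaustively in
tests. The survivor set is not guaranteed to match any particular reference
tool SNP-for-SNP; downstream analysis depends only on approximate linkage
equilibrium, not on which twin of a correlated pair survives.

### Locus-based replication

A discovered pair is replicated at locus rather than SNP resolution:
`locus_replicate()` tests every cross-locus pair between windows (default
±100 kb) around the two discovery coordinates, Bonferroni-corrects the best
P value for the number of cross-locus pairs tested, and declares replication
below α = 0.05. The window default comfortably covers the tens-of-kb
distances at which a replication panel's best proxy for an untyped discovery
SNP typically sits; within-locus pairs never enter the count, and the result
is invariant to swapping the two loci.

## The simulator: what it emulates, and what it does not

`simulation_spec()` + `simulate_cohort()` generate cohorts with exactly the
structure the analysis assumes:

* genotypes in HWE at chosen MAFs, drawn per SNP from two latent haplotype
  Gaussians; an AR(1) correlation `ld_rho` along the SNP index induces
  tunable local LD (0.8–0.9 gives realistic block structure) while keeping
  marginal HWE exact. This latent-threshold model was chosen over haplotype
  resampling because it is analytically transparent and needs no external
  reference data; the pipeline only requires tunable pairwise r².
* covariates: age ~ U(45, 64) years, sex ~ Bernoulli(0.5), BMI ~ N(28, 4.5²)
  kg/m² — a middle-aged cardiovascular-cohort profile.
* trait: `Y = 50 − 0.05·age + 8·sex − 0.4·BMI + genetic terms + N(0, 6.5²)`
  by default, giving a mean near 40 mg/dl and SD near 7.8 mg/dl, an HDL-like
  scale for a dyslipidemic population.
* missingness: per-sample and per-SNP Bernoulli masks applied *after* the
  trait is generated — missingness emulates assay failure, not biology.

Effect sizes can be given as coefficients or as target fractions of total
trait variance. The conversion is analytic: for an additive fraction `v` at
MAF p the coefficient is `sqrt(v·V_T / 2p(1−p))`, and for interaction terms
the denominator is the variance of the interaction column *residualized
against the marginal space* — under independence the centered cross-product
is uncorrelated with every marginal code, so this variance is just the
product of the two marginal-term variances. That choice is what makes a
planted "pure interaction of 1%" recover a `delta_r2` of ~1%: the marginal
model soaks up the projection of the raw product column onto main effects,
and only the residualized part is left for the interaction terms to explain.
With LD switched on, or several overlapping interaction terms, the realized
fractions drift from their targets and tests use wider tolerances.

One master seed drives everything; per-stage streams (genotypes,
covariates, phenotype, missingness) are derived from it with fixed offsets,
so each stage reproduces in isolation and whole pipelines are bit-identical
across runs.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real cohorts: population stratification and relatedness,
genotyping batch effects, haplotype-scale LD beyond AR(1) decay,
non-Gaussian trait tails, and selection-based ascertainment (the motivating
candidate-gene cohort was recruited on a mixed-dyslipidemia profile, i.e. a
truncated trait distribution; trait truncation is out of scope here and a
known limitation).

## Calibration and power, concretely

The test suite recomputes, at every run:

* agreement of the scan's F and p with a generic nested-least-squares
  oracle to 1e-8 relative on 200 random problems;
* type-I error at α = 0.05 over 5,000 null replicates (n = 1,000, MAFs
  0.3/0.4, covariates and marginal effects active) within [0.042, 0.058],
  plus a Kolmogorov-Smirnov uniformity check on the null P values;
* mean recovered `delta_r2` within [0.8%, 1.2%] for a planted 1% pure
  interaction at n = 10,000 over 100 replicates, with empirical power
  matching the noncentral-F closed form (noncentrality
  `λ = n·v·V_T/σ²`) within Monte-Carlo error;
* a scale rehearsal — an all-pairs scan of 304 SNPs × 2,091 samples
  (~46,000 enumerated pairs) and a hub scan of one anchor against 10,000
  partners at n = 9,713 — in which the planted signals rank first.

Those problem sizes were chosen to mirror the cohort scales the method
targets while staying comfortable on a single CPU.

```{r quick-demo}
set.seed(42)
maf <- c(0.3, 0.4, runif(18, 0.2, 0.5))
spec <- simulation_spec(
  n_samples = 2000, maf = maf, n_snps = 20,
  interactions = data.frame(snp1 = 1, snp2 = 2, v_aa = 0.02),
  seed = 42)
sim <- simulate_cohort(spec)
scan <- all_pairs_scan(sim$genotypes, sim$cohort)
glance(scan)
tidy(scan) |> select(snp1, snp2, F, p, p_bonferroni, delta_r2) |> head(3)
```

## Numerical notes

* Least squares go through rank-revealing pivoted QR (`qr()` with tolerance
  1e-9); aliased columns are dropped with the rank recorded, never silently
  imputed.
* The scan's batch path residualizes genotype columns against the covariate
  design once (Frisch-Waugh-Lovell) and fits small per-pair QRs; the
  one-pair path builds the full design directly. The two routes agree to
  1e-8 relative and the batch path falls back to the one-pair path whenever
  a pair has missing genotypes.
* The HWE exact test evaluates the conditional heterozygote-count
  distribution by the stable ratio recurrence, started at the mode;
  enumeration via log-factorials agrees to 1e-9 across every count triple
  with total ≤ 200.
* Results TSVs print 17 significant digits so a write-read round trip is
  exact, and rows sort by (p, snp1, snp2) so output order is deterministic
  under any parallel partitioning of the pair list.
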