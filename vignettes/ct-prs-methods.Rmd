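---
title: "Methods: C+T polygenic scores and their evaluation in prsonset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: C+T polygenic scores and their evaluation in prsonset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`prsonset` implements a clumping-and-thresholding (C+T) polygenic risk
score pipeline for major-depression genetic liability, evaluated inside an
Alzheimer's cohort against two endpoints: depression case status
(logistic/ROC) and depression onset age (left-truncated survival). This
vignette is the package's account of the methods, the conventions it
fixes where the field leaves slack, and what its synthetic cohorts do and
do not demonstrate.

## Score construction

### Variant funnel

Summary statistics pass an imputation-quality filter (`filter_info()`,
strict `INFO > 0.9`; the strictness is configurable). Target-cohort
variants pass `qc_variants()`: MAF > 0.01, call rate > 0.95,
Hardy–Weinberg p > 1e-6, and — when a reference panel frequency is
supplied — an absolute allele-frequency difference of at most 0.20. The
first three cuts are strict inequalities, the frequency difference is
inclusive, matching the usual statement of these thresholds. Removals are
reported by first-failing criterion in the order call rate, MAF, HWE,
reference difference; survivorship itself is a conjunction, so the
reported order never changes which variants survive. HWE defaults to the
1-df goodness-of-fit chi-square on best-guess hard calls (dosages rounded
to the nearest integer); a conditional exact test (mid-p by default) is
available via `hwe_test(..., method = "exact")` and serves as a
rank-ordering cross-check in the tests.

`harmonize()` aligns GWAS betas to the allele each target dosage counts:
exact match keeps the beta, swapped alleles negate it, strand-complement
matches are complemented first, and strand-ambiguous pairs (A/T, C/G) are
dropped by default — their complement equals their swap, so orientation
cannot be decided; on INFO-filtered imputed data the loss is small.
Matching is by variant id with a `chrom:pos` fallback.

`mask_region()` removes the APOE region, chr19:45,111,942–45,711,941 on
GRCh37 (±300 kb around the APOE epsilon coding SNPs), both ends
inclusive, so the depression score cannot simply tag the strongest
Alzheimer's locus.

`clump()` is greedy: the smallest-p unassigned variant becomes an index
(ties broken by position, then id, making output deterministic), and
unassigned same-chromosome variants within ±250 kb with dosage r² > 0.1
are assigned to its clump. r² is computed from the target cohort's own
dosages over pairwise-complete samples — no external LD reference is
required, though one can be supplied as a second genotype matrix. The
p-value thresholds use the inclusive convention `p <= threshold`; the
canonical sweep is the 14-value list `prs_thresholds()`.

### The two formulas

The standard score is `Σ β·X`. The risk-increasing score reorients each
variant to its risk allele (`G = X` when β > 0, else `G = 2 − X`, with
`β⁺ = |β|`) and computes `(Σ β⁺·G) · T / Σ β⁺`. The denominator sums the
*reoriented positive* betas: under the signed-sum reading the denominator
can be zero or negative and the score loses its meaning as a scaled
average of risk alleles, so the positive-orientation reading is adopted.
Zero-beta variants carry no risk orientation and are excluded from `T`
and the beta sum (counted in an attribute). Per fixed variant set the two
formulas are affinely related with positive slope, hence identical
rankings and identical AUC — asserted to 1e-12 in the tests.

Missing data follow the score-time zero rule: a selected GWAS variant
absent from the target, and any per-sample missing dosage, contributes
zero — most of the population carries at least one copy of the major
allele, which zero effect-allele copies approximate. For the
risk-increasing formula the zero applies to the risk-allele count G (a
missing genotype contributes no risk alleles), not to `2 − X`. Genotype
readers deliberately keep missing entries as `NA`; zero-filling is owned
by the scoring step alone.

Scores enter association models standardized within cohort (sample-SD,
n−1 convention). Survival effects are reported per SD for the standard
score and per risk allele (unstandardized) for the risk-increasing score,
which is the interpretable scale that formula exists for.

## Evaluation

Threshold selection fits the standalone logistic model `case ~ PRS` at
every threshold and picks the largest (most positive) standardized PRS
coefficient — an effect-size criterion, not minimal p; ties go to the
smaller threshold. Whether to maximize the standardized or raw-scale
coefficient is genuinely open; the standardized coefficient is used
because raw-scale coefficients are not comparable across thresholds (the
score's variance grows with the variant count).

AUC is the Mann–Whitney statistic with ties counting one half, computed
from midranks and verified against exhaustive pair enumeration. It is
in-sample (no cross-validation), matching how such single-cohort analyses
are typically reported; the validation cohort, scored at the frozen
discovery threshold, is the out-of-sample check. Nested models with and
without the PRS are compared with a two-sided paired DeLong test
implemented from placement values; identical predictors return p = 1 by
convention. Population structure is adjusted with the top three
components of the dosage matrix standardized by `2p` and `√(2p(1−p))`,
computed on the QC-passed clumped variant set, with a fixed sign
convention (largest-magnitude loading positive) so runs are
bit-reproducible. Case/control score means are compared with a one-sided
Welch t-test (alternative: cases higher); Welch because equal variances
are not guaranteed and the cost under equality is negligible. The APOE
ε3/ε3 stratum repeats the models with the `e4_count` term dropped (it is
constant zero there).

### Time-to-event

The time axis is age, not time-on-study: subjects enter observation at
their study entry age (left truncation) and exit at depression onset or
last visit. `fit_ph_left_truncated()` maximizes the Cox partial
likelihood with delayed-entry risk sets (entry < t ≤ exit), Breslow tie
handling by default (Efron behind a flag; the choice is immaterial at the
tie densities simulated here). `km_curve()` is the product-limit
estimator with the same risk sets, reported from the first age at which
the at-risk count reaches a documented minimum (default 1). The k-group
log-rank test with delayed entry is implemented in the package directly —
the classical implementations commonly accept only right-censored input —
and is cross-checked against `survival::survdiff` when entry is zero and
against the Cox score test under truncation. Tertiles cut at the
empirical 1/3 and 2/3 quantiles (R type-7), boundary values to the lower
group; with 10 distinct scores this yields sizes 4/3/3.

## The synthetic cohorts

The generator (`sim_config()` and friends) emulates the *structure* of a
two-cohort PRS study so the pipeline is testable without restricted data.

**Genotypes.** Variants come in LD blocks assigned round-robin to
chromosomes 1–22, blocks 1 Mb apart (so distinct blocks never share a
clumping window), variants 5 kb apart within a block, and one block
pinned inside the APOE region so the mask always has work to do. Within a
block every haplotype allele copies a block "template" haplotype with
probability `sqrt(within_block_r)` and otherwise draws fresh at the block
MAF. This makes marginal frequencies exact and gives any two variants in
a block dosage correlation `within_block_r` (r² = `within_block_r²`,
e.g. 0.81 at the 0.9 default check level). A thresholded latent Gaussian
was considered first but rejected: dichotomizing attenuates correlation
(tetrachoric 0.9 yields dosage r² near 0.5 at MAF 0.3), so the latent
correlation would no longer be the user-facing dial. Allele labels are a
deterministic function of variant index, so cohorts simulated over the
same map agree on them, as cohorts genotyped on one panel do; a
`template_variants` argument reuses a previous cohort's map, MAFs and
alleles for discovery/validation pairs.

**Summary statistics.** A fraction `causal_fraction` of variants gets
Normal(0, `effect_sd`²) true effects; estimated betas add noise with
`SE = 1/√(2·n_gwas·maf·(1−maf))`, the standard binary-trait GWAS
standard-error scale at effective sample size `n_gwas` (default 156,000,
the scale of a large MDD meta-analysis). P-values are the two-sided
normal test of beta/SE; INFO is uniform on [0.5, 1], so the INFO > 0.9
filter removes about 80% of records.

**Phenotype.** Liability is `a·z_g + Σ c_k·z_k + e` with standardized
true genetic score `z_g`, standardized covariates, and standard-normal
residual; `a` is set so the genetic share of liability variance equals
`genetic_var_share` (an explicit config field; default 0.10, a realistic
order for an MDD score in a small cohort). A subject is a case when
liability exceeds the normal quantile matching the prevalence (default
0.36, the roughly one-case-per-two-controls structure of depression in
Alzheimer's samples). Covariate marginals are Alzheimer's-cohort-like:
age Normal(81.5, 6.7²), education Normal(16.2, 3.7²), 68% female, APOE
allele frequencies e2/e3/e4 = 0.06/0.69/0.25 (ε4-enriched, as in an
Alzheimer's sample), childhood financial need ordinal 1–5.

**Onset.** Onset age is `60 + Exponential(rate)` with
`rate = baseline_hazard · exp(prs_log_hazard · z)`; entry age is
Normal(81.5, 6.7²) truncated above 61, follow-up uniform 2–12 years,
censoring at last visit. Subjects whose onset precedes entry are redrawn
(entry and onset jointly) — rejection sampling that mimics
prevalent-cohort recruitment and is the generator's left-truncation
contract. Real incidence rates for depression within Alzheimer's
follow-up are not established, so `baseline_hazard` (default 0.05 per
person-year) is a free structural parameter, not a calibrated one.

One integer seed fans out to fixed per-stage substreams (genotypes,
effects, summary statistics, phenotype, onset), so any stage can be
regenerated independently and identical seed + config gives bit-identical
cohorts.

**What passing tests show.** The synthetic cohorts validate the
*machinery*: selection logic, score algebra, model fitting, truncation
handling, calibration of the tests. They use exchangeable block LD, a
single homogeneous population (a 2-component mixture only in the PCA
tests), no imputation-error structure, and exponential baseline hazards —
so passing says nothing about real human LD patterns, portability across
ancestries, or the true effect size of any MDD score in any cohort.

## Numerical conventions and problem sizes

Degenerate inputs fail loudly: constant scores cannot be standardized or
tertiled, single-class outcomes cannot be fit, rank-deficient designs
name their collinear columns, `entry == exit` survival rows are rejected,
and zero-event cohorts mark the survival section undefined rather than
fitting. p = 0 summary rows are clamped to the smallest positive double
and counted. Monomorphic variants get HWE p = 1 with a flag; zero-variance
r² is 0 with a flag.

The shipped analyses use 2,000 samples × 5,000 variants per cohort, the
package's default simulation size: large enough that the funnel, sweep,
PCA and survival stages all engage meaningfully, small enough to run in
about a minute. Parameter-recovery tests use n = 5,000–20,000 where the
estimator's sampling error at that size is well inside the asserted
tolerance; the liability-model AUC check compares against a Monte-Carlo
oracle value (0.6462 at variance share 0.10, prevalence 0.36) precomputed
from 10 × 200,000 draws.

## Known limitations

No beta shrinkage (LDpred-style) or dominance encodings; no sample-level
QC (relatedness, sex checks); no genotype imputation — dosage input is
taken as given; no competing-risk handling for death before depression;
the DeLong comparison is of in-sample fitted probabilities, which is
anticonservative for nested models and is why the validation cohort
exists in the design.
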