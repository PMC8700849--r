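---
title: "Evaluating the discriminative and prognostic value of a polygenic risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the discriminative and prognostic value of a polygenic risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsperf)
```

## The problem

A polygenic risk score (PRS) condenses the common-variant genetic
liability for a complex disease into one number per individual: the sum
of allele dosages weighted by per-allele log-odds effect sizes
estimated in a discovery GWAS. Two distinct questions arise when such a
score is taken to an independent cohort. First, *validity*: does the
score still separate cases from controls, and which of its variants
carry that separation? Second, *prognostic value*: if a healthy
individual's score is high, how likely are they actually to develop the
disease during their remaining lifetime? The two questions have very
different answers for late-onset, low-incidence diseases such as
Parkinson's disease, and this package implements the full analysis
chain for both.

## Score computation and standardization

Variants in the weight table are matched to the genotype panel by
(chromosome, position); a match additionally requires that the weight
table's allele pair equals the panel's \{ref, alt\} set, and that the
variant passes a minor-allele-frequency filter (default 0.01) and,
when the panel carries imputation info scores, an info filter (default
0.7). Matching by position alone would silently mis-score variants
whose alleles disagree, so the allele-set requirement is imposed even
though it is stricter than position-only matching; when alleles agree
it changes nothing. Strand-ambiguous (A/T, C/G) pairs are matched
as-is with a warning rather than frequency-flipped: silent strand
flipping invents information the data do not contain.

Dosages always count the panel's alt allele. When a weight's effect
allele is the panel's ref allele the dosage enters the sum as `2 - d`;
the match report records the orientation per variant so the decision is
visible. Missing dosages are mean-imputed as twice the effect-allele
frequency of the non-missing dosages (restricted to controls when
control IDs are supplied), with a drop-variant-per-individual
alternative; imputed panels normally have no missingness, but a policy
must exist and must be explicit.

Raw scores are standardized by subtracting the mean and dividing by the
standard deviation of the score *among controls*, so one score unit is
one control SD. The SD uses the sample convention (denominator
n − 1); the choice is not critical since any threshold downstream is
expressed in the same units. Standardization parameters are stored in
the result so new individuals can be placed on the same scale.

## Discrimination statistics

The case-control analysis regresses status on the standardized score
adjusted for sex, age at sampling and the first three principal
components, by maximum likelihood (IRLS with relative log-likelihood
tolerance 1e-10, at most 100 iterations). Wald tests are two-sided and
no multiple-testing correction is applied anywhere. Nagelkerke's
pseudo-R² rescales Cox–Snell, `1 - exp(2 (l0 - l1)/n)`, by its
attainable maximum `1 - exp(2 l0 / n)`; it is reported for the model
with and without the score, both against the intercept-only null.

The ROC curve places thresholds at midpoints between consecutive
distinct scores, with ±Inf sentinels; "test-positive" means score
strictly above the threshold. The AUC is the Mann–Whitney statistic
with ties counted ½ — exactly the probability that a random case
outscores a random control — and its 95% CI uses the DeLong placement
variance. The implementation is rank-based (midranks), which the test
suite verifies against exhaustive pair counting and against pROC's
DeLong interval to 1e-10.

Decile odds ratios use cut points at the 10%…90% type-7 quantiles of
the *control* score distribution; bins are right-closed, so a score
tied with a boundary falls into the lower decile. ORs are unadjusted
2×2 cross-product ratios against the lowest decile with Wald CIs
`exp(log OR ± 1.96 √(Σ 1/cell))`; covariate-adjusted decile ORs would
be a different estimand and are deliberately not computed (the output
records this convention). Zero cells raise an error rather than a
silent continuity correction.

The age-at-onset analysis splits cases at the type-7 onset quartiles,
keeps Q1 (onset ≤ 25th percentile) and Q4 (onset > 75th percentile),
and repeats the logistic fit with early-onset membership as outcome —
without age at sampling, which would be collinear with onset — plus the
score's Q1-vs-Q4 ROC/AUC.

## Most relevant variants

Step 1 computes "AUC-SNP" values: for each variant, the AUC of the
score with that variant excluded. Step 2 runs greedy backward
elimination: among the remaining variants, remove the one whose
exclusion yields the lowest residual AUC, recompute the residual
score's DeLong CI, and stop the first time that CI includes 0.5; the
removed variants, in removal order, are the most relevant set. The
candidate scan is recomputed over the remaining set at every iteration
(full greedy); a `recompute = FALSE` switch reuses the initial ranking
for speed when the full scan is too costly. Ties in the steepest
decline are broken by genomic (chromosome, position) order, so reruns
are bit-identical. If the CI never includes 0.5 the procedure stops
with one variant left and flags the result rather than looping.

Numerically, sub-scores are row sums over a precomputed per-variant
contribution matrix (weight × oriented dosage). The retained columns
are summed afresh at every evaluation instead of subtracting the
removed contribution from a running total: with integer dosages many
individuals share identical sub-scores, and incremental subtraction
perturbs those exact ties by one ulp, which moves tie-counted AUCs by
~1/(n_case · n_control) and can redirect the greedy path. Fresh
summation keeps the procedure exactly equal to explicit rescoring
(verified against a naive oracle on random instances), at O(m² n) per
elimination scan — entirely adequate at the scales analysed here; at
biobank scale one would accept the subtraction approximation.

Step 3 (`rank_table`) sorts variants by AUC-SNP and cross-classifies
the most relevant set against an externally supplied genome-wide
significance annotation; the count of most-relevant variants is a
data-dependent outcome of the stopping rule, not a parameter.

## Prognostic analysis

Thresholds come from maximizing the weighted Youden index
`costs · sensitivity + specificity` over the ROC curve, with `costs ≥ 1`
the relative severity of a false negative (a missed future case)
against a false positive. At `costs = 1` this is the classic Youden
point. Exact ties are resolved towards higher sensitivity. The cost
grid spans 1 to 5 in steps of 0.0001 (40001 points, generated by
integer indexing so the last grid value is exactly 5); sensitivity is
non-decreasing and specificity non-increasing along the grid, which the
implementation checks rather than assumes.

For screening healthy individuals, the relevant pre-test probability is
not cross-sectional prevalence but the *residual lifetime incidence*:
the probability that a currently disease-free individual of age *d*
develops the disease before dying. From a life table of ten 5-year
intervals [50–54] … [95+] with interval incidence I and annual death
probability D, each interval's survival factor is approximated as
S = (1 − D)⁵ and the residual incidence accumulates each later
interval's incidence discounted by all earlier survival and
disease-free factors. The implementation uses the backward recursion
`R_k = I_k + S_k (1 − I_k) R_{k+1}` with `R_10 = I_10`, which
telescopes into the direct sum (the test suite checks the equality on
random tables to 1e-12). The terminal open interval contributes its
incidence once, with no further survival weighting, and intervals are
treated as contiguous 5-year bins throughout. Predictive values then
follow from Bayes' formula with the age group's residual incidence as
prior; a 0/0 denominator (e.g. the ppv of an all-negative test) is
reported as undefined (`NA`), never as 0.

Two consequences are worth internalizing: npv = 1 *exactly* whenever
sensitivity is 1, regardless of incidence (the false-negative term
vanishes), and an all-negative "nonsense test" already achieves
npv = 1 − incidence, so a high npv alone says little about a screening
test when incidence is a few percent.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with known ground truth. Genotypes are Hardy–Weinberg allele-count
dosages at frequencies drawn from a configurable range (integer counts
by default; fractional imputation-style noise is an opt-in flag, since
integer dosages suffice to exercise the downstream mathematics).
Disease status follows a logistic model on the *standardized* true
score plus sex and age; using the standardized score decouples the
per-SD effect from the number of variants, which keeps parameter
recovery well-defined across simulation sizes. Case age-at-onset is
normal with mean decreasing in the true score. A master seed fans out
into per-stage child seeds so stages can be regenerated independently;
identical seeds give bit-identical studies.

Default calibration (chosen once, by numerical integration of the
tilted score densities under case-control sampling, before any test
was run): per-SD log-OR 0.57 with baseline log-odds qlogis(0.25), sex
effect 0.35 and age effect 0.02/yr over ages U(40, 80) yields a
case-control AUC ≈ 0.65; an onset slope of −1.3 yr per score SD with
onset SD 10 yields a Q1-vs-Q4 onset AUC ≈ 0.59 — the discrimination
scale reported for validated Parkinson's disease scores. The default
study shape is 1914 cases / 4464 controls and 1743 variants,
overridable for fast tests. The packaged life-table profile is a
synthetic stand-in calibrated only in magnitude (residual lifetime
incidence ≈ 1.9% at 50, 0.2% at 95+, the scale of claims-data
Parkinson rates); it is not a transcription of any published table.
Control ages are uniform because no distributional fact is available to
copy; weights are Gaussian with a small fraction of inflated-SD
"large-effect" variants.

What the generator does *not* emulate — linkage disequilibrium between
variants, population stratification (the PCs are pure noise
covariates), relatedness, genotyping batch effects — bounds what
passing tests show: they validate the statistical machinery, not
robustness to the correlation structure of real genotype data.

## Problem sizes and numerical conventions

The test suite runs the full pipeline at the default study shape
(6378 individuals × 1743 variants) once, parameter recovery at
20000 × 200, and oracle equivalences on many small instances
(n ≤ 300, ≤ 8 variants) where exhaustive enumeration is exact.
Quantiles are type 7 everywhere. Logistic separation and non-full-rank
designs raise errors naming the covariate. All randomness flows from
explicit integer seeds.

## Limitations

Sensitivity/specificity CIs on the Youden operating points are not
computed (bootstrap settings would be guesswork), and ppv/npv are
reported without intervals. The prognostic table is a theoretical
construction from a life table, not an empirical long-term validation.
PLINK/BGEN inputs and genome-build liftover are out of scope; the
weight and dosage formats carry 1-based, VCF-convention coordinates.
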