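---
title: "Pathway-focused SNP association: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-focused SNP association: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pathscan implements a pathway-focused association workflow for hypertension
and blood pressure: instead of hunting genome-wide significant single SNPs,
it asks whether an *a priori* biological pathway (a set of genes, hence a
set of SNPs) harbours an excess of moderately significant variants
(p between 1e-2 and 1e-5), pooled through an LD-aware set statistic and
judged against a phenotype-permutation null.  This vignette is the
package's own account of the statistical machinery, the tunable
parameters, the synthetic cohort it is validated on, and the places where
a genuine design choice had to be made.

## The per-SNP model

Each SNP is coded additively as the dosage of its minor allele (0/1/2;
males on the X chromosome are hemizygous and coded 0/1, a heterozygous
male call being treated as missing since it is biologically invalid).
For hypertension case status the model is maximum-likelihood logistic
regression; for systolic and diastolic pressure it is ordinary least
squares on medication-adjusted values:

    outcome ~ dosage + sex + age + age^2 + BMI

The reported statistic is the 1-df Wald chi-square `(beta/se)^2` with a
two-sided p-value from the chi-square(1) survival function (for the linear
model too: at the sample sizes this package targets the t-versus-normal
distinction is negligible, and a single reference distribution keeps the
permutation machinery uniform).  Missing dosages are handled complete-case
per SNP, matching the convention of standard GWAS tooling.  SNPs that are
monomorphic among analyzed samples are *flagged* and assigned p = 1 rather
than dropped, so set sizes remain stable in downstream tables.  Age enters
uncentered as `age` and `age^2` (the literal covariate list); a centering
option exists for numerical conditioning but is off by default.

Case status is systolic pressure >= 140 mmHg, diastolic >= 90 mmHg, or
current antihypertensive medication.  For the continuous analyses only,
treated individuals' pressures are adjusted by +15 mmHg (systolic) and
+10 mmHg (diastolic) to approximate untreated values; the adjustment can
never change the case definition because medication alone classifies.

## Quality control

SNP filters run first, in order — missingness > 0.05, minor allele
frequency < 1%, exact Hardy-Weinberg test p < 1e-6 — each counted on the
survivors of the previous filter; then samples with homozygosity-based
inbreeding coefficient further than 4 SD from the cohort mean are removed,
with F computed on the surviving SNPs.  Design choices worth recording:

* **Exact HWE test, not chi-square.**  At an alpha of 1e-6 the chi-square
  approximation is unreliable in exactly the tail that matters; the exact
  two-sided test sums the probabilities of all heterozygote configurations
  (given the allele counts) no more probable than the observed one.  The
  distribution is computed with a cumulative-sum recurrence in log space
  (stable for thousands of samples), and probability comparisons use a
  1e-9 relative tolerance so mathematically tied configurations are never
  split by floating-point round-off.  On X, only females enter the test.
* **Inbreeding estimator.**  The conventional method-of-moments F from
  observed versus expected homozygosity, with the small-sample n/(n-1)
  allele-frequency correction, over polymorphic autosomal SNPs.  No
  iteration between SNP and sample filters is performed (single pass).

## The set-based permutation test

For a SNP set (pathway or gene) with per-SNP p-values and the pairwise
dosage r-squared matrix:

1. pick the most significant SNP; stop if its p exceeds the `P_SNP`
   cutoff (default 0.05);
2. eliminate remaining SNPs with r-squared above the LD threshold
   (default 0.5) against the pick — one signal per locus;
3. repeat; the *set statistic* is the mean 1-df chi-square statistic of
   the selected SNPs, 0 if none ("N Sig" is the selected count).

Permuted datasets are created by swapping the phenotype labels across
individuals — covariates stay attached to their individuals — and the
whole procedure (per-SNP statistics, greedy selection) is re-run on each;
LD is a property of the genotypes and is computed once, never re-permuted.
The empirical p-value is `(1 + #{permuted >= observed}) / (n_perm + 1)`,
the add-one form that can never return 0 and counts ties against the
observed statistic.  With exhaustive enumeration (all distinct
case/control labelings, feasible for tiny n) the exact proportion is
reported instead, the observed labeling being one of the enumerated ones.
Ties in the greedy min-p step are broken by (chromosome, position) order
for determinism.  Quantitative traits permute the (medication-adjusted)
phenotype vector — the continuous analogue of label swapping.

Multiplicity is handled by Bonferroni at each level: alpha/28 pathways
(0.002 at display precision), alpha/101 genes (0.0005), alpha/4349 SNPs
(1.15e-5) in the full-scale design this mirrors.

**Statistic modes.**  `wald_refit` refits the full model per SNP per
permutation and is the reference mode.  `score_fast` evaluates the score
test of adding each dosage to the null covariates-only model: for the
linear model the dosages are residualized against the covariates once and
each permutation costs one matrix-vector product; for the logistic model
one small null GLM is refit per permutation (the covariate-outcome
relation changes under permutation) and all per-SNP score statistics
follow by linear algebra.  The observed statistic is always computed in
the *same* mode as the permuted ones, preserving exchangeability.  Missing
dosages are mean-imputed inside the score engine only (a few samples per
SNP after QC); Wald fits stay complete-case.  `auto` switches to
`score_fast` above 1e5 SNP-fits.  The two modes agree in set ranking
(Spearman >= 0.95 on a graded synthetic benchmark, enforced in the test
suite).

**What the empirical p is, and is not.**  When no SNP meets the selection
cutoff the set statistic is 0 and the empirical p is exactly 1.00 — the
"N Sig 0, P 1.00" row pattern.  Under a null cohort this produces a point
mass at 1 (about a third of 20-SNP sets at the default cutoff), so the
empirical p distribution is *sub*-uniform by construction, not uniform:
the meaningful calibration checks, which the acceptance suite runs, are
(i) a one-sided Kolmogorov-Smirnov test that the p-values are not
stochastically *smaller* than uniform (anti-conservatism would be the
actual error) and (ii) the lower-tail type-I fraction at 0.05.  Exact
two-sided uniformity is additionally verified in the property suite at
`P_SNP` cutoff 1, where selection never stops early and the empirical p
reduces to an exchangeable rank — there it *is* uniform up to the
1/(n_perm+1) grid.

## Genetic risk score

For the selected SNPs of one outcome, each SNP's *unfavorable* allele is
its minor allele when the effect is risk-increasing (OR > 1, beta > 0)
and its major allele otherwise.  A person's score is r_i/n_i: unfavorable
alleles carried over total alleles counted, all SNPs weighted equally.
Missing genotypes drop out of both numerator and denominator (per-sample
denominators vary) rather than biasing scores toward 0.  Scores are cut
at their 20/40/60/80th percentiles — boundary values fall to the lower
quintile, and a degenerate (empty) quintile is an error naming the tied
break — and the outcome is regressed on quintile indicators plus the
standard covariates, lowest quintile as reference.  The score is
in-sample by construction (built from SNPs selected on the same data) and
is validated here as a *pattern* — increasing quintile estimates on
planted-effect cohorts — not as an individually calibrated predictor.

## The synthetic cohort

No genotype data from the motivating study are distributable, so the
package carries a seeded generator that emulates the *structure* the
analysis assumes; its defaults are the stated world of the validation
suite and were fixed before any acceptance measurement:

* 1,614 samples, 49.4% hypertensive, 50.1% of cases on medication, 58.2%
  female; age ~ N(49, 14.5) truncated at 18; BMI ~ N(24.1, 5.4) truncated
  above 14; height ~ N(1.64, 0.08) with weight derived from BMI.
* 28 pathways x 4 genes x 39 SNPs (~4.4k SNPs, mirroring the full-scale
  28/101/4,349 design); MAF uniform on (0.05, 0.5); 1% random
  missingness.
* **LD:** haplotypes are thresholded latent Gaussians with exchangeable
  within-block correlation (5 SNPs per block by default); two independent
  haplotypes sum to a dosage, so genotypes satisfy HWE by construction.
  The latent correlation is calibrated by numerically inverting the
  orthant probability so the *indicator* (phi) correlation hits the
  square root of the target r-squared at the block's mean MAF — realized
  dosage r-squared is therefore approximate, and the test suite asserts a
  band (0.35-0.65 for a 0.5 target), not a point.
* **Effects:** causal SNPs (a fraction of one causal pathway, default 8%)
  receive log odds ratios drawn from OR 1.15-1.30 — sized to make single
  SNPs *moderately* significant at n = 1614, the regime the method
  targets — and positive mmHg-per-allele effects (1.0-2.5) on both
  pressures, so disease and pressure associations co-occur with shared
  direction, as a real causal pathway's would.  The case-status intercept
  is solved numerically so the marginal prevalence matches the target
  exactly given the realized linear predictor.
* **Coherence of case labels and pressures.**  Case status is drawn from
  the logistic liability, but the phenotype file format carries no case
  column — status must be recoverable from pressures and medication via
  the standard definition.  The generator reconciles the two by
  reflecting pressures across the 140/90 thresholds for the minority of
  samples whose simulated BP contradicts their drawn label (after
  rounding to the 0.1 mmHg measurement grid, so rounding cannot undo a
  reflection).  Treated cases store their underlying pressures minus
  15/10 mmHg, so the pipeline's medication adjustment is exercised.  The
  reflection mildly distorts the BP tails and attenuates continuous-trait
  effects for the reconciled subset; it does not touch genotypes, and
  case-control analyses are unaffected.
* All randomness flows from one root seed through named substreams
  (genotypes, covariates, phenotypes, missingness), so stages are
  individually reproducible and the whole cohort is bit-identical per
  seed.

What the generator does **not** emulate — and what a green test therefore
does not establish — includes population structure and admixture (the
motivating cohort showed no stratification), genotyping batch and plate
effects, differential missingness by phenotype, relatedness, and
realistic recombination-driven LD decay (blocks are exchangeable and
independent).  QC filters that exist to catch such artefacts
(sex-discordance, IBD pruning, MDS outliers, batch tests) are
correspondingly out of scope.

## Numerical choices and degenerate inputs

* Gene flanks: 20 kb each side, coordinates 1-based, bounds *inclusive*
  at both the interval and the flank edge (the convention is not fully
  pinned down by gene-list formats; inclusivity was chosen and is
  asserted at the exact boundary in the tests).
* Minor-allele orientation is recomputed from the data on every read; an
  exact 0.5 frequency tie keeps the file's coding, for determinism.
* Undefined LD r-squared (constant dosage vector) is treated as 0: an
  uninformative SNP can never justify pruning another.
* A set with zero SNPs is retained (n_snps = 0) and reported with
  empirical p 1.00 without running permutations.
* Logistic non-convergence/separation flags the result (`converged =
  FALSE`, no effect reported) instead of emitting a huge spurious odds
  ratio; inside permutations such fits contribute statistic 0.
* Bonferroni cutoffs are exact divisions; rounding (0.002, 0.0005,
  1.15e-5) happens only in display helpers.

## Configuration surface

Runs are driven by a single declarative JSON config (`run_config()` /
`read_run_config()`); the seed is mandatory and never defaulted silently.
YAML was the obvious alternative but no YAML parser is available in the
package's dependency budget, and JSON round-trips the same content.
The `pathscan_cli()` dispatcher exposes `simulate`, `qc`, `assoc`,
`settest`, `riskscore` and `run` subcommands mirroring the stage
functions.

## Known limitations

* The score engine's mean imputation of missing dosages differs from the
  Wald path's complete-case handling; after QC (missingness <= 5%) the
  discrepancy is small and the reference mode is always available.
* Permutation of a quantitative trait assumes exchangeability of the
  adjusted phenotype given covariates; a Freedman-Lane style residual
  permutation would be more robust under strong covariate effects and is
  a natural extension point.
* The risk score is in-sample; out-of-sample validation (cross-validated
  selection) is deliberately out of scope.
* Empirical p-values inherit the 1/(n_perm+1) floor; pathway-level
  conclusions at the 0.002 cutoff need n_perm >= 10,000, the default.
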