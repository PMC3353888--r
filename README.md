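# pathscan

Pathway-focused SNP association analysis for hypertension and blood
pressure in R.

Genome-wide association studies of blood pressure have struggled to find
single variants of large effect: blood pressure is tightly regulated, and
its genetic architecture appears to be many variants of small effect.
`pathscan` implements the complementary strategy — test *a priori*
biological pathways (sets of genes, hence sets of SNPs) for an excess of
moderately significant variants (10⁻² > p > 10⁻⁵), too weak to survive
genome-wide multiple-testing correction individually but informative in
aggregate.  It is aimed at statistical geneticists and methods students
who want a tested, reproducible, end-to-end implementation of this
workflow, including a synthetic cohort generator so everything runs
without access to any real genotype data.

## What it computes

**Per-SNP association.**  Additive minor-allele dosage models with
covariate adjustment, fit per SNP:

    logit P(HTN = 1) = β₀ + β·g + γ₁·sex + γ₂·age + γ₃·age² + γ₄·BMI
    SBP (or DBP)     = β₀ + β·g + γ₁·sex + γ₂·age + γ₃·age² + γ₄·BMI + ε

with Wald 1-df chi-square statistics, hemizygous 0/1 coding for males on
X, and +15/+10 mmHg medication adjustment of SBP/DBP for treated
individuals (continuous analyses only).

**Set-based permutation test** (pathway and gene level).  Greedy
selection of the most significant SNP, LD pruning of SNPs with r² above
a threshold (default 0.5), repeat until the next SNP misses the P_SNP
cutoff (default 0.05); set statistic = mean chi-square of the selected
SNPs; empirical p from phenotype-label permutations:

    P_set = (1 + #{permuted set statistic ≥ observed}) / (n_perm + 1)

with Bonferroni cutoffs per family (0.05/28 pathways ≈ 0.002, 0.05/101
genes ≈ 0.0005, 0.05/4349 SNPs ≈ 1.15×10⁻⁵ at full scale) and a
Default/Strict/Loose sensitivity grid over (r², P_SNP).

**QC.**  SNP missingness > 0.05, MAF < 1%, exact Hardy–Weinberg test
p < 10⁻⁶ (enumeration-exact, log-space recurrence), then sample
inbreeding coefficient beyond ±4 SD.

**Genetic risk score.**  Per person, the fraction rᵢ/nᵢ of unfavorable
alleles (minor allele of risk SNPs, major allele of protective SNPs)
over the selected SNP panel, analyzed by quintile in adjusted regression
against the lowest quintile.

**Synthetic cohorts.**  Seeded generator with block LD from thresholded
latent Gaussians, study-matched demographics (n = 1614, 49.4%
hypertensive, 58.2% female), and small planted effects concentrated in
one causal pathway.  See the vignette (`vignettes/pathway-association.Rmd`)
for the model and its limits.

## Worked example

Simulate a cohort of 1,614 with one causal pathway among six, run QC and
the pathway-level permutation test, then the risk-score quintile model:

```r
library(pathscan)

spec <- simulation_spec(
  n_samples = 1614,
  pathways = data.frame(name = sprintf("PW%02d", 1:6),
                        n_genes = 3, snps_per_gene = 12),
  causal_pathway = "PW03", causal_snp_fraction = 0.25,
  effect_or_range = c(1.2, 1.35), seed = 2024)
sim <- simulate_cohort(spec)
qc  <- apply_qc(sim$cohort)

params <- set_test_params(n_perm = 2000, seed = 2024,
                          stat_mode = "score_fast")
res <- run_level(qc$cohort, sim$pathways, params,
                 outcomes = c("HTN", "DBP"))
```

The pathway table (HTN empirical p ascending):

```
  set n_snps n_sig        emp_p   emp_p_DBP
 PW03     36     8 0.0004997501 0.006496752
 PW02     36     1 0.0504747626 0.059970015
 PW01     36     0 1.0000000000 1.000000000
 PW04     36     0 1.0000000000 1.000000000
 PW05     36     0 1.0000000000 0.192403798
 PW06     36     0 1.0000000000 1.000000000
```

The planted pathway PW03 selects 8 LD-independent SNPs ("N Sig") and its
empirical p, 0.0005 = 1/2001, is the permutation floor — well below the
Bonferroni cutoff 0.05/6 ≈ 0.0083 — while the null pathways either select
nothing (empirical p exactly 1.00 by the empty-selection convention) or
hover at chance.  The shared-direction planted effects also surface in
the DBP column.  Building the risk score from PW03's selected SNPs:

```r
a   <- assoc_scan(qc$cohort, model_spec("HTN"))
sel <- observed_selection(sim$pathways$PW03, qc$cohort,
                          model_spec("HTN"), params)
qm  <- quintile_model(score_samples(qc$cohort, build_risk_model(a, sel)),
                      qc$cohort$samples, model_spec("HTN"))
round(qm$estimates, 3)
#>  quintile estimate    se ci_lo ci_hi     p
#>         1    1.000    NA    NA    NA    NA
#>         2    1.164 0.173 0.830 1.634 0.379
#>         3    1.512 0.166 1.092 2.094 0.013
#>         4    1.728 0.155 1.275 2.343 0.000
#>         5    3.614 0.180 2.540 5.142 0.000
```

Odds of hypertension rise monotonically with the unfavorable-allele
ratio; the top quintile carries ~3.6-fold the odds of the bottom quintile
(95% CI 2.5–5.1), the qualitative pattern a genuine causal pathway
produces.  `run_all(run_config(...))` executes the same stages — plus
gene-level tests, the sensitivity grid and rendered markdown tables —
from one declarative config, and `pathscan_cli()` exposes each stage as a
subcommand.

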