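Package: pathscan
Title: Pathway-Focused SNP Association Analysis with Set-Based Permutation Tests
Version: 0.1.0
Authors@R:
    person("pathscan", "authors", email = "pathscan@example.org",
           role = c("aut", "cre"))
Description: Tools for pathway-focused genetic association studies of
    hypertension and blood pressure: per-SNP additive logistic and linear
    regression with covariate adjustment, SNP and sample quality control
    (missingness, minor allele frequency, exact Hardy-Weinberg test,
    inbreeding coefficient), LD-aware set-based permutation tests at the
    pathway and gene level with sensitivity grids and Bonferroni cutoffs,
    an unfavorable-allele-ratio genetic risk score with quintile models,
    and a seeded synthetic cohort generator with block LD structure for
    end-to-end testing.  Reads and writes PLINK text and binary genotype
    formats and optionally VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
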