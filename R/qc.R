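#' QC thresholds
#'
#' Container for the SNP- and sample-level quality-control thresholds:
#' maximum per-SNP missingness 0.05, minimum minor allele frequency 1%,
#' exact Hardy-Weinberg test alpha 1e-6, and sample inbreeding coefficient
#' within 4 standard deviations of the cohort mean.
#'
#' @param max_snp_missing exclude SNPs with missingness strictly above this.
#' @param min_maf exclude SNPs with MAF strictly below this.
#' @param hwe_alpha exclude SNPs with exact HWE p strictly below this.
#' @param inbreeding_sd exclude samples with |F - mean(F)| above this many
#'   SDs.
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_snp_missing = 0.05, min_maf = 0.01,
                          hwe_alpha = 1e-6, inbreeding_sd = 4) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_alpha > 0, hwe_alpha <= 1, inbreeding_sd > 0)
  structure(list(max_snp_missing = max_snp_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, inbreeding_sd = inbreeding_sd),
            class = "qc_thresholds")
}

#' Per-SNP missingness
#'
#' Proportion of samples with a missing genotype call, per SNP.
#'
#' @param cohort a `cohort`.
#' @param snp optional SNP id(s) or column index; default all SNPs.
#' @return named numeric vector of proportions.
#' @export
snp_missingness <- function(cohort, snp = NULL) {
  g <- cohort$genotypes
  if (!is.null(snp)) g <- g[, snp, drop = FALSE]
  colMeans(is.na(g))
}

#' Minor allele frequency
#'
#' Folded allele frequency from allele counts: (het + 2 hom-minor) /
#' (2 n_nonmissing) on autosomes; on X, males are hemizygous and contribute
#' a single allele each.  Values above 0.5 (coded allele actually major) are
#' folded to `1 - f`.
#'
#' @inheritParams snp_missingness
#' @return named numeric vector of frequencies in \[0, 0.5\].
#' @export
minor_allele_freq <- function(cohort, snp = NULL) {
  g <- cohort$genotypes
  copies <- .allele_copies(cohort)
  if (!is.null(snp)) {
    g <- g[, snp, drop = FALSE]
    copies <- copies[, snp, drop = FALSE]
  }
  copies[is.na(g)] <- NA_integer_
  den <- colSums(copies, na.rm = TRUE)
  if (any(den == 0)) stop("all-missing SNP(s): ",
                          paste(colnames(g)[den == 0], collapse = ", "))
  f <- colSums(g, na.rm = TRUE) / den
  pmin(f, 1 - f)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on genotype counts: conditional on the observed
#' allele counts, the probability of every heterozygote configuration is
#' computed under the Hardy-Weinberg (hypergeometric-type) null, and the
#' p-value is the sum of the probabilities of all configurations no more
#' probable than the observed one.  The distribution over heterozygote
#' counts of matching parity is evaluated with a numerically stable
#' cumulative-product recurrence; probability ties are counted using a 1e-9
#' relative tolerance so symmetric configurations are never split by
#' round-off.
#'
#' @param hom_major,het,hom_minor non-negative genotype counts.
#' @return exact two-sided p-value in (0, 1].
#' @export
hwe_exact_p <- function(hom_major, het, hom_minor) {
  if (any(c(hom_major, het, hom_minor) < 0)) stop("negative genotype counts")
  n <- hom_major + het + hom_minor
  if (n < 1) stop("empty genotype table")
  n_a <- 2 * hom_minor + het            # rare-allele count (fold if needed)
  if (n_a > n) n_a <- 2 * n - n_a
  if (n_a == 0) return(1.0)
  dist <- .hwe_het_dist(n_a, n)
  obs <- dist$prob[match(het, dist$het)]
  if (is.na(obs)) stop("heterozygote count has impossible parity")
  min(1, sum(dist$prob[dist$prob <= obs * (1 + 1e-9)]))
}

# distribution of heterozygote count given rare-allele count n_a and n
# diploid samples; ratio recurrence P(h+2)/P(h) = (na-h)(nb-h)/((h+2)(h+1))
.hwe_het_dist <- function(n_a, n) {
  n_b <- 2 * n - n_a
  h <- seq.int(n_a %% 2, min(n_a, n_b), by = 2)
  if (length(h) == 1) return(list(het = h, prob = 1))
  hh <- h[-length(h)]
  lp <- cumsum(c(0, log((n_a - hh) * (n_b - hh)) - log((hh + 2) * (hh + 1))))
  lp <- lp - max(lp)                     # log-space: stable for large N
  p <- exp(lp)
  p <- p / sum(p)
  list(het = h, prob = p)
}

#' Exact HWE p-values for every SNP in a cohort
#'
#' On chromosome X only females enter the test (males are hemizygous).
#' Monomorphic SNPs return 1.
#'
#' @param cohort a `cohort`.
#' @return numeric vector of p-values, one per variant.
#' @export
hwe_scan <- function(cohort) {
  g <- cohort$genotypes
  on_x <- cohort$variants$chrom == "X"
  female <- if ("sex" %in% names(cohort$samples))
    !is.na(cohort$samples$sex) & cohort$samples$sex == "female"
  else rep(TRUE, nrow(g))
  vapply(seq_len(ncol(g)), function(j) {
    gj <- if (on_x[j]) g[female, j] else g[, j]
    gj <- gj[!is.na(gj)]
    if (!length(gj)) return(NA_real_)
    hwe_exact_p(sum(gj == 0L), sum(gj == 1L), sum(gj == 2L))
  }, numeric(1))
}

#' Sample inbreeding coefficient
#'
#' Method-of-moments F from observed vs expected homozygosity over a
#' sample's non-missing autosomal SNPs:
#' `F = (O_hom - E_hom) / (L - E_hom)`, where for SNP j with cohort allele
#' frequency `p_j` estimated from `n_j` non-missing alleles the expected
#' homozygosity uses the small-sample correction
#' `1 - 2 p_j (1 - p_j) n_j / (n_j - 1)`.  Monomorphic SNPs are excluded.
#'
#' @param cohort a `cohort`.
#' @param sample optional sample id(s)/index; default all samples.
#' @return named numeric vector of F estimates.
#' @export
inbreeding_coefficient <- function(cohort, sample = NULL) {
  auto <- cohort$variants$chrom != "X"
  g <- cohort$genotypes[, auto, drop = FALSE]
  nonmiss <- !is.na(g)
  n_al <- 2 * colSums(nonmiss)
  p <- colSums(g, na.rm = TRUE) / n_al
  keep <- p > 0 & p < 1 & n_al > 2
  g <- g[, keep, drop = FALSE]
  nonmiss <- nonmiss[, keep, drop = FALSE]
  if (!ncol(g)) stop("no polymorphic autosomal SNPs for inbreeding F")
  e_j <- 1 - 2 * p[keep] * (1 - p[keep]) * n_al[keep] / (n_al[keep] - 1)
  hom <- !is.na(g) & g != 1L
  o_hom <- as.numeric(hom %*% rep(1, ncol(g)))
  e_hom <- as.numeric(nonmiss %*% e_j)
  l_used <- rowSums(nonmiss)
  if (any(l_used == 0)) stop("sample(s) with no usable genotypes")
  if (any(abs(l_used - e_hom) < 1e-12)) stop("degenerate E_hom = L")
  f <- (o_hom - e_hom) / (l_used - e_hom)
  names(f) <- cohort$samples$id
  if (!is.null(sample)) f <- f[sample]
  f
}

#' Concordance between duplicate genotype vectors
#'
#' Proportion of matching calls over entries non-missing in both vectors
#' (same variant order assumed).
#'
#' @param g1,g2 dosage vectors.
#' @return proportion in \[0, 1\].
#' @export
duplicate_concordance <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no comparable (jointly non-missing) entries")
  mean(g1[ok] == g2[ok])
}

#' Apply SNP and sample quality control
#'
#' Single-pass filtering in the conventional order: SNP filters first
#' (missingness, then MAF, then exact HWE, each counted on the survivors of
#' the previous filter), then the sample inbreeding-coefficient filter
#' computed on the surviving SNPs.  Variant annotations are recomputed on
#' the filtered cohort.
#'
#' @param cohort a `cohort`.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with elements `cohort` (filtered) and `report` (data.frame
#'   of removal counts per criterion, in application order).
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds()) {
  miss <- snp_missingness(cohort)
  drop_miss <- miss > thresholds$max_snp_missing
  kept <- which(!drop_miss)
  maf <- minor_allele_freq(cohort, kept)
  drop_maf <- kept[maf < thresholds$min_maf]
  kept <- setdiff(kept, drop_maf)
  hwe <- hwe_scan(subset_cohort(cohort, variants = kept))
  drop_hwe <- kept[!is.na(hwe) & hwe < thresholds$hwe_alpha]
  kept <- setdiff(kept, drop_hwe)
  if (!length(kept)) stop("all SNPs removed by QC")
  co <- subset_cohort(cohort, variants = kept)
  f <- inbreeding_coefficient(co)
  bad_f <- abs(f - mean(f)) > thresholds$inbreeding_sd * sd(f)
  bad_f[is.na(bad_f)] <- FALSE          # sd = 0 when all F identical
  if (all(bad_f)) stop("all samples removed by QC")
  co <- subset_cohort(co, samples = which(!bad_f))
  co <- annotate_variants(co)
  report <- data.frame(
    criterion = c("snp_missingness", "snp_maf", "snp_hwe",
                  "sample_inbreeding"),
    removed = c(sum(drop_miss), length(drop_maf), length(drop_hwe),
                sum(bad_f)),
    threshold = c(thresholds$max_snp_missing, thresholds$min_maf,
                  thresholds$hwe_alpha, thresholds$inbreeding_sd))
  list(cohort = co, report = report)
}
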