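# Independent oracles used across the suite.  These deliberately take the
# brute-force / closed-form route rather than sharing code with the package.

# Exact HWE test by direct enumeration: multinomial probability of every
# heterozygote configuration given the allele counts, via lgamma.
oracle_hwe <- function(hom_major, het, hom_minor) {
  n <- hom_major + het + hom_minor
  n_a <- 2 * hom_minor + het
  if (n_a > n) n_a <- 2 * n - n_a
  if (n_a == 0) return(1.0)
  n_b <- 2 * n - n_a
  h <- seq.int(n_a %% 2, min(n_a, n_b), by = 2)
  lp <- lgamma(n + 1) - lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_b - h) / 2 + 1) + h * log(2) +
    lgamma(n_a + 1) + lgamma(n_b + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(het, h)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# all heterozygote-count p-values for one (rare allele count, N) pair,
# vectorized (for exhaustive sweeps)
oracle_hwe_all <- function(n_a, n) {
  n_b <- 2 * n - n_a
  h <- seq.int(n_a %% 2, min(n_a, n_b), by = 2)
  lp <- lgamma(n + 1) - lgamma((n_a - h) / 2 + 1) - lgamma(h + 1) -
    lgamma((n_b - h) / 2 + 1) + h * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  sapply(p, function(po) min(1, sum(p[p <= po * (1 + 1e-9)])))
}

# score statistic for a binary outcome with intercept-only null model
# (Cochran-Armitage-type trend statistic), used as the independent per-SNP
# statistic in the brute-force set-test oracle
oracle_score_stat <- function(y, g) {
  ph <- mean(y)
  w <- ph * (1 - ph)
  u <- sum(g * (y - ph))
  v <- w * (sum(g^2) - sum(g)^2 / length(g))
  if (v <= 0) return(0)
  u^2 / v
}

# plain-loop reimplementation of the greedy LD-pruned selection
oracle_greedy <- function(stats, r2, stat_cut, r2_threshold) {
  remaining <- seq_along(stats)
  sel <- integer(0)
  while (length(remaining)) {
    best <- remaining[order(-stats[remaining])][1]
    if (stats[best] < stat_cut) break
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
    remaining <- remaining[r2[remaining, best] <= r2_threshold]
  }
  sel
}

# exhaustive set-based permutation test over all case labelings, built on
# the two oracles above; returns the exact empirical p
oracle_set_test_exact <- function(y, g, r2, p_cutoff, r2_threshold) {
  stat_cut <- qchisq(p_cutoff, df = 1, lower.tail = FALSE)
  set_stat <- function(yy) {
    stats <- apply(g, 2, function(gj) oracle_score_stat(yy, gj))
    sel <- oracle_greedy(stats, r2, stat_cut, r2_threshold)
    if (length(sel)) mean(stats[sel]) else 0
  }
  obs <- set_stat(y)
  labelings <- combn(length(y), sum(y == 1))
  stats <- apply(labelings, 2, function(ci) {
    yy <- numeric(length(y)); yy[ci] <- 1
    set_stat(yy)
  })
  mean(stats >= obs - 1e-12)
}

# small deterministic cohort constructor for unit tests
make_test_cohort <- function(g, chrom = NULL, pos = NULL, sex = NULL,
                             samples = NULL) {
  n <- nrow(g); m <- ncol(g)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variants <- data.frame(id = sprintf("s%03d", seq_len(m)), chrom = chrom,
                         pos = pos, minor_allele = "A", major_allele = "G",
                         stringsAsFactors = FALSE)
  if (is.null(samples)) {
    samples <- data.frame(id = sprintf("I%03d", seq_len(n)),
                          stringsAsFactors = FALSE)
    samples$sex <- if (is.null(sex)) rep("female", n) else sex
  }
  new_cohort(g, variants, samples, validate = FALSE)
}

# small phenotyped cohort via the generator (shared by several files)
small_sim <- function(seed, n = 300, n_pathways = 3, n_genes = 2,
                      snps_per_gene = 8, ...) {
  simulate_cohort(simulation_spec(
    n_samples = n,
    pathways = data.frame(name = sprintf("PW%02d", seq_len(n_pathways)),
                          n_genes = n_genes,
                          snps_per_gene = snps_per_gene),
    seed = seed, ...))
}
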