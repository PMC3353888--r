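#' Simulation specification for a synthetic cohort
#'
#' The defaults encode the cohort the analysis was designed around: 1,614
#' unrelated adults, ~49.4% hypertensive with ~50.1% of cases on
#' antihypertensive medication, 58.2% female, age ~ N(49, 14.5) truncated
#' at 18, BMI ~ N(24.1, 5.4) truncated above 14; 28 pathways tiling 4
#' genes x 39 SNPs each (~4.4k SNPs, the study's ~4,349), block LD from a
#' thresholded latent Gaussian, MAF uniform on (0.05, 0.5); and small
#' per-SNP effects (odds ratios 1.15-1.30, i.e. moderately significant
#' single-SNP p-values at this sample size) concentrated in one causal
#' pathway with shared direction across HTN/SBP/DBP.
#'
#' @param n_samples cohort size.
#' @param pathways data.frame `name, n_genes, snps_per_gene` (genes are
#'   pathway-private in the generator).
#' @param ld_block_size SNPs per LD block (blocks never span genes).
#' @param ld_r2_target within-block dosage r^2 aimed for (realized r^2 is
#'   approximate; the latent correlation is calibrated at the block's mean
#'   MAF).
#' @param maf_range range minor allele frequencies are drawn from.
#' @param causal_pathway name of the pathway carrying effects, or `NA` for
#'   a null cohort.
#' @param causal_snp_fraction fraction of the causal pathway's SNPs given
#'   effects.
#' @param effect_or_range per-SNP odds-ratio range for hypertension.
#' @param effect_beta_range per-SNP mmHg-per-allele range for SBP/DBP.
#' @param covariate_effects list of coefficient vectors (`sex_male, age,
#'   age2, bmi`, covariates centered) per outcome `htn/sbp/dbp`.
#' @param baseline_prevalence target marginal case fraction.
#' @param missing_rate genotype missingness, completely at random.
#' @param medication_rate_in_cases treated fraction among cases.
#' @param sbp_sd,dbp_sd residual SDs of the continuous traits (mmHg).
#' @param seed root seed; all stages draw from named substreams derived
#'   from it.
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 1614,
                            pathways = data.frame(
                              name = sprintf("PW%02d", 1:28),
                              n_genes = 4, snps_per_gene = 39),
                            ld_block_size = 5, ld_r2_target = 0.5,
                            maf_range = c(0.05, 0.5),
                            causal_pathway = "PW01",
                            causal_snp_fraction = 0.08,
                            effect_or_range = c(1.15, 1.30),
                            effect_beta_range = c(1.0, 2.5),
                            covariate_effects = list(
                              htn = c(sex_male = 0.2, age = 0.05,
                                      age2 = 0, bmi = 0.08),
                              sbp = c(sex_male = 3, age = 0.5,
                                      age2 = 0, bmi = 0.8),
                              dbp = c(sex_male = 1.5, age = 0.25,
                                      age2 = 0, bmi = 0.6)),
                            baseline_prevalence = 0.494,
                            missing_rate = 0.01,
                            medication_rate_in_cases = 0.501,
                            sbp_sd = 24, dbp_sd = 14,
                            seed = NULL) {
  if (is.null(seed)) stop("simulation_spec: a seed is required")
  stopifnot(ld_r2_target >= 0, ld_r2_target < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate <= 1,
            baseline_prevalence > 0, baseline_prevalence < 1,
            medication_rate_in_cases >= 0, medication_rate_in_cases <= 1,
            causal_snp_fraction >= 0, causal_snp_fraction <= 1)
  structure(list(n_samples = as.integer(n_samples), pathways = pathways,
                 ld_block_size = as.integer(ld_block_size),
                 ld_r2_target = ld_r2_target, maf_range = maf_range,
                 causal_pathway = causal_pathway,
                 causal_snp_fraction = causal_snp_fraction,
                 effect_or_range = effect_or_range,
                 effect_beta_range = effect_beta_range,
                 covariate_effects = covariate_effects,
                 baseline_prevalence = baseline_prevalence,
                 missing_rate = missing_rate,
                 medication_rate_in_cases = medication_rate_in_cases,
                 sbp_sd = sbp_sd, dbp_sd = dbp_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# named substream seeds derived from the root seed
.substreams <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 4),
           c("genotypes", "covariates", "phenotypes", "missingness"))
}

# phi (point) correlation of two equal-frequency threshold indicators of a
# bivariate normal with correlation rho: 1-D Gaussian quadrature of the
# orthant probability.
.phi_corr <- function(rho, p) {
  if (rho <= 0) return(0)
  t <- qnorm(p)
  p11 <- integrate(function(w)
    dnorm(w) * pnorm((t - sqrt(rho) * w) / sqrt(1 - rho))^2,
    -8, 8, rel.tol = 1e-10)$value
  (p11 - p^2) / (p * (1 - p))
}

# latent exchangeable correlation whose thresholded indicators have
# squared phi correlation ~ target_r2 at frequency p
.latent_rho <- function(target_r2, p) {
  if (target_r2 <= 0) return(0)
  r_target <- sqrt(target_r2)
  uniroot(function(rho) .phi_corr(rho, p) - r_target,
          lower = 1e-9, upper = 1 - 1e-9, tol = 1e-8)$root
}

#' Simulate genotypes, gene intervals and pathways
#'
#' Haplotypes are generated per LD block by thresholding exchangeably
#' correlated standard normals at each SNP's allele-frequency quantile; two
#' independent haplotypes per individual are summed into dosages, so
#' genotypes are Hardy-Weinberg consistent by construction.  Blocks are
#' independent; genes tile consecutive blocks; genes are spaced 120 kb
#' apart (SNPs 4 kb apart) so the 20 kb flanking rule is exercised without
#' cross-gene capture, and each gene's declared interval is 2 kb inside its
#' terminal SNPs so those SNPs are only recovered through the flank.
#' Missing calls are injected completely at random.
#'
#' @param spec a [simulation_spec()].
#' @return list: `genotypes` (matrix), `variants`, `genes` (interval
#'   data.frame), `pathway_df` (pathway, gene memberships), `sample_ids`.
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$maf_range[1] <= 0 || spec$maf_range[2] > 0.5)
    stop("maf_range outside (0, 0.5]")
  streams <- .substreams(spec$seed)
  pw <- spec$pathways
  gene_tab <- do.call(rbind, lapply(seq_len(nrow(pw)), function(i)
    data.frame(pathway = pw$name[i],
               gene = sprintf("%s_G%02d", pw$name[i],
                              seq_len(pw$n_genes[i])),
               n_snps = pw$snps_per_gene[i], stringsAsFactors = FALSE)))
  n_genes <- nrow(gene_tab)
  genes_per_chrom <- max(1L, ceiling(n_genes / 22))
  n <- spec$n_samples

  set.seed(streams["genotypes"])
  snp_spacing <- 4000L
  gene_gap <- 120000L
  geno_cols <- list(); var_rows <- list(); gene_rows <- list()
  rho_cache <- new.env(parent = emptyenv())
  snp_counter <- 0L
  pos_cursor <- 1e6L
  cur_chrom <- 1L
  genes_on_chrom <- 0L
  for (gi in seq_len(n_genes)) {
    if (genes_on_chrom >= genes_per_chrom && cur_chrom < 22L) {
      cur_chrom <- cur_chrom + 1L
      genes_on_chrom <- 0L
      pos_cursor <- 1e6L
    }
    m <- gene_tab$n_snps[gi]
    pos <- pos_cursor + snp_spacing * (seq_len(m) - 1L)
    maf <- runif(m, spec$maf_range[1], spec$maf_range[2])
    gmat <- matrix(0L, n, m)
    blocks <- split(seq_len(m),
                    ceiling(seq_len(m) / spec$ld_block_size))
    for (bl in blocks) {
      pbar <- mean(maf[bl])
      key <- sprintf("%.4f", pbar)
      rho <- if (!is.null(rho_cache[[key]])) rho_cache[[key]]
             else (rho_cache[[key]] <- .latent_rho(spec$ld_r2_target, pbar))
      t_j <- qnorm(maf[bl])
      hap <- matrix(0L, n, length(bl))
      for (h in 1:2) {
        w <- rnorm(n)
        z <- sqrt(rho) * w +
          sqrt(1 - rho) * matrix(rnorm(n * length(bl)), n)
        hap <- hap + (sweep(z, 2, t_j, `<`)) * 1L
      }
      gmat[, bl] <- hap
    }
    ids <- sprintf("snp%05d", snp_counter + seq_len(m))
    snp_counter <- snp_counter + m
    geno_cols[[gi]] <- gmat
    var_rows[[gi]] <- data.frame(id = ids, chrom = as.character(cur_chrom),
                                 pos = pos, minor_allele = "A",
                                 major_allele = "G",
                                 stringsAsFactors = FALSE)
    gene_rows[[gi]] <- data.frame(gene = gene_tab$gene[gi],
                                  chrom = as.character(cur_chrom),
                                  start = pos[1] + 2000L,
                                  end = pos[m] - 2000L,
                                  stringsAsFactors = FALSE)
    genes_on_chrom <- genes_on_chrom + 1L
    pos_cursor <- pos[m] + gene_gap
  }
  genotypes <- do.call(cbind, geno_cols)
  variants <- do.call(rbind, var_rows)
  genes <- do.call(rbind, gene_rows)
  genes$end <- pmax(genes$end, genes$start)      # tiny genes stay valid

  if (spec$missing_rate > 0) {
    set.seed(streams["missingness"])
    drop <- runif(length(genotypes)) < spec$missing_rate
    genotypes[drop] <- NA_integer_
  }
  list(genotypes = genotypes, variants = variants, genes = genes,
       pathway_df = gene_tab[, c("pathway", "gene")],
       sample_ids = sprintf("S%05d", seq_len(n)))
}

#' Simulate phenotypes and covariates for generated genotypes
#'
#' Covariates follow the study demographics (see [simulation_spec()]).
#' Hypertension is drawn from a logistic liability with per-SNP log odds
#' ratios on the causal SNPs and centered covariate effects, the intercept
#' solved so the marginal prevalence matches `baseline_prevalence`.
#' SBP/DBP are linear in the same causal dosages (shared effect direction)
#' with Gaussian noise; blood pressures are then reconciled with the drawn
#' case status by reflecting values across the 140/90 mmHg thresholds for
#' the few samples whose simulated BP contradicts it, so that the standard
#' case definition (BP thresholds or medication) recovers the liability
#' label exactly.  Medication is assigned among cases, and treated
#' individuals' stored raw pressures are their underlying values minus
#' 15/10 mmHg, so the downstream medication adjustment is exercised.
#'
#' @param geno result of [simulate_genotypes()] (or a compatible list with
#'   `genotypes`, `variants`, `pathway_df`, `sample_ids`, `genes`).
#' @param spec the same [simulation_spec()].
#' @return a prepared sample table (see [prepare_samples()]) with attribute
#'   `"truth"` describing the planted causal SNPs and effects.
#' @export
simulate_phenotypes <- function(geno, spec) {
  streams <- .substreams(spec$seed)
  n <- length(geno$sample_ids)

  set.seed(streams["covariates"])
  sex <- ifelse(runif(n) < 0.582, "female", "male")
  age <- qnorm(runif(n, pnorm(18, 49, 14.5), 1), 49, 14.5)
  height <- pmin(pmax(rnorm(n, 1.64, 0.08), 1.35), 2.05)
  bmi <- qnorm(runif(n, pnorm(14, 24.1, 5.4), 1), 24.1, 5.4)
  weight <- bmi * height^2

  # planted effects
  set.seed(streams["phenotypes"])
  causal_ids <- character(0); log_or <- beta_sbp <- beta_dbp <- numeric(0)
  eta_g_htn <- eta_g_sbp <- eta_g_dbp <- numeric(n)
  if (!is.na(spec$causal_pathway) && spec$causal_snp_fraction > 0) {
    genes_in <- geno$pathway_df$gene[geno$pathway_df$pathway ==
                                       spec$causal_pathway]
    if (!length(genes_in)) stop("causal pathway not found: ",
                                spec$causal_pathway)
    gmap <- assign_snps_to_genes(geno$variants, geno$genes)
    pool <- unique(unlist(gmap[genes_in], use.names = FALSE))
    if (!length(pool)) stop("causal pathway has no SNPs")
    k <- max(1L, round(spec$causal_snp_fraction * length(pool)))
    causal_ids <- sort(sample(pool, k))
    ci <- match(causal_ids, geno$variants$id)
    log_or <- runif(k, log(spec$effect_or_range[1]),
                    log(spec$effect_or_range[2]))
    beta_sbp <- runif(k, spec$effect_beta_range[1], spec$effect_beta_range[2])
    beta_dbp <- runif(k, spec$effect_beta_range[1], spec$effect_beta_range[2])
    gc_mat <- geno$genotypes[, ci, drop = FALSE]
    storage.mode(gc_mat) <- "double"
    gc_mat[is.na(gc_mat)] <- matrix(colMeans(gc_mat, na.rm = TRUE),
                                    n, k, byrow = TRUE)[is.na(gc_mat)]
    gc_mat <- sweep(gc_mat, 2, colMeans(gc_mat))
    eta_g_htn <- as.numeric(gc_mat %*% log_or)
    eta_g_sbp <- as.numeric(gc_mat %*% beta_sbp)
    eta_g_dbp <- as.numeric(gc_mat %*% beta_dbp)
  }

  cv <- function(co) {
    co <- co[c("sex_male", "age", "age2", "bmi")]
    male <- as.numeric(sex == "male")
    a_c <- age - mean(age)
    co["sex_male"] * (male - mean(male)) + co["age"] * a_c +
      co["age2"] * (a_c^2 - mean(a_c^2)) + co["bmi"] * (bmi - mean(bmi))
  }
  eta_htn <- eta_g_htn + cv(spec$covariate_effects$htn)
  b0 <- uniroot(function(b) mean(plogis(b + eta_htn)) -
                  spec$baseline_prevalence, c(-20, 20))$root
  htn <- runif(n) < plogis(b0 + eta_htn)
  on_med <- htn & runif(n) < spec$medication_rate_in_cases

  sbp <- 131.7 + eta_g_sbp + cv(spec$covariate_effects$sbp) +
    rnorm(n, 0, spec$sbp_sd)
  dbp <- 81.25 + eta_g_dbp + cv(spec$covariate_effects$dbp) +
    rnorm(n, 0, spec$dbp_sd)

  # reconcile BP with the liability-drawn case label (see vignette);
  # round to the measurement grid first so reflections cannot be undone
  sbp <- round(sbp, 1); dbp <- round(dbp, 1)
  fix_case <- htn & !on_med & sbp < 140 & dbp < 90
  sbp[fix_case] <- 280 - sbp[fix_case]
  fix_ctrl_s <- !htn & sbp >= 140
  sbp[fix_ctrl_s] <- pmax(280 - sbp[fix_ctrl_s] - 0.1, 90)
  fix_ctrl_d <- !htn & dbp >= 90
  dbp[fix_ctrl_d] <- pmax(180 - dbp[fix_ctrl_d] - 0.1, 55)

  sbp_raw <- sbp - ifelse(on_med, 15, 0)
  dbp_raw <- dbp - ifelse(on_med, 10, 0)

  samples <- prepare_samples(data.frame(
    id = geno$sample_ids, sex = sex, age = age, weight_kg = weight,
    height_m = height, bmi = bmi, sbp = sbp_raw,
    dbp = dbp_raw, on_med = on_med, phenotyped = TRUE,
    stringsAsFactors = FALSE))
  stopifnot(identical(unname(samples$hypertensive), unname(htn)))
  attr(samples, "truth") <- list(
    causal_pathway = spec$causal_pathway, causal_snps = causal_ids,
    log_or = log_or, beta_sbp = beta_sbp, beta_dbp = beta_dbp,
    intercept_htn = b0, seed = spec$seed)
  samples
}

#' Simulate a complete cohort
#'
#' Wires [simulate_genotypes()] and [simulate_phenotypes()] into a `cohort`
#' plus its gene intervals, pathway memberships, resolved pathway SNP sets
#' and the planted-truth manifest.  Bit-identical for a given spec.
#'
#' @param spec a [simulation_spec()].
#' @param flank_bp flank used to resolve pathway SNP sets.
#' @return list: `cohort`, `genes`, `pathway_df`, `pathways`
#'   ([build_pathways()] output), `truth`.
#' @export
simulate_cohort <- function(spec, flank_bp = 20000L) {
  geno <- simulate_genotypes(spec)
  samples <- simulate_phenotypes(geno, spec)
  truth <- attr(samples, "truth")
  attr(samples, "truth") <- NULL
  co <- new_cohort(geno$genotypes, geno$variants, samples, validate = FALSE)
  co <- orient_to_minor(co)
  co <- annotate_variants(co)
  gmap <- assign_snps_to_genes(co$variants, geno$genes, flank_bp)
  pathways <- build_pathways(geno$pathway_df, gmap)
  list(cohort = co, genes = geno$genes, pathway_df = geno$pathway_df,
       pathways = pathways, gene_map = gmap, truth = truth)
}

#' Write a simulated cohort plus truth manifest
#'
#' Writes the cohort in a [write_cohort()] format together with
#' `genes.tsv`, `pathways.tsv` and `truth.json` (the planted causal SNPs
#' and effects, for recovery tests).
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created).
#' @param format genotype format.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir,
                             format = c("plink_text", "plink_binary",
                                        "vcf")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, file.path(dir, "cohort"), match.arg(format))
  write.table(sim$genes, file.path(dir, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$pathway_df, file.path(dir, "pathways.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
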