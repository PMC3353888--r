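test_that("pairwise_r2: identity, symmetry, brute-force value, degenerate", {
  d <- c(0, 1, 2, 1, 0)
  expect_equal(pairwise_r2(d, d), 1)
  expect_equal(pairwise_r2(d, c(2, 1, 0, 1, 2)), 1)   # perfect negative
  d1 <- c(0, 1, 2, 1); d2 <- c(0, 1, 2, 2)
  expect_equal(pairwise_r2(d1, d2), cor(d1, d2)^2)
  expect_equal(pairwise_r2(c(1, 1, 1, 1), d1), 0)     # constant -> 0
  expect_equal(pairwise_r2(c(0, NA, NA, 1), c(0, 1, NA, NA)), 0)  # 1 shared
})

test_that("greedy_select reproduces a hand-traced 5-SNP run", {
  p <- c(0.001, 0.002, 0.03, 0.2, 0.04)
  r2 <- diag(5)
  r2[1, 2] <- r2[2, 1] <- 0.9   # 2 pruned by 1
  r2[1, 5] <- r2[5, 1] <- 0.3
  r2[3, 5] <- r2[5, 3] <- 0.6   # 5 pruned by 3
  # trace: pick 1 (p=.001), prune 2; pick 3 (.03), prune 5; 4 fails cutoff
  expect_equal(greedy_select(p, r2, 0.05, 0.5), c(1L, 3L))
  # matches the independent loop oracle
  stats <- qchisq(p, 1, lower.tail = FALSE)
  expect_equal(greedy_select(p, r2, 0.05, 0.5),
               oracle_greedy(stats, r2, qchisq(0.05, 1, lower.tail = FALSE),
                             0.5))
  expect_equal(greedy_select(rep(0.5, 5), diag(5), 0.05, 0.5), integer(0))
  # two SNPs in perfect LD, both significant -> only the better one
  expect_equal(greedy_select(c(0.01, 0.001), matrix(1, 2, 2), 0.05, 0.5),
               2L)
})

test_that("selected SNPs respect the pruning rule across random cases", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- 12
    p <- runif(m)^2
    r <- cor(matrix(rnorm(40 * m), 40, m))
    r2 <- r^2; diag(r2) <- 1
    sel <- greedy_select(p, r2, 0.1, 0.4)
    if (length(sel) > 1)
      for (k in 2:length(sel))
        expect_true(all(r2[sel[k], sel[seq_len(k - 1)]] <= 0.4))
    expect_true(all(p[sel] <= 0.1))
  }
})

test_that("empty and zero-SNP sets follow the n_sig = 0 => p = 1.00 rule", {
  sim <- small_sim(21, n = 120, n_pathways = 1, snps_per_gene = 4)
  res0 <- set_based_test(list(name = "empty", snp_ids = character(0)),
                         sim$cohort, model_spec("HTN"),
                         set_test_params(n_perm = 50, seed = 1))
  expect_equal(res0$n_sig, 0L)
  expect_equal(res0$emp_p, 1)
  expect_equal(res0$n_perm, 0L)
})

test_that("exhaustive enumeration equals the brute-force oracle", {
  # 8 samples, 3 SNPs, intercept-only model, all C(8,4) labelings
  g <- matrix(c(0, 1, 2, 0, 1, 2, 0, 1,
                2, 2, 1, 0, 0, 1, 0, 0,
                1, 0, 0, 1, 2, 0, 1, 1), 8, 3)
  y <- c(1, 1, 0, 0, 1, 0, 1, 0)
  co <- make_test_cohort(g)
  co$samples$phenotyped <- TRUE
  co$samples$hypertensive <- y == 1
  params <- set_test_params(r2_threshold = 0.5, p_cutoff = 0.5,
                            perm_method = "exhaustive",
                            stat_mode = "score_fast", seed = 1)
  spec <- model_spec("HTN", covariates = character(0))
  res <- set_based_test(list(name = "toy", snp_ids = co$variants$id),
                        co, spec, params)
  r2 <- ld_r2_matrix(g)
  expect_equal(res$n_perm, choose(8, 4))
  expect_equal(res$emp_p, oracle_set_test_exact(y, g, r2, 0.5, 0.5),
               tolerance = 1e-12)

  # singleton set: exact permutation p of that one SNP
  res1 <- set_based_test(list(name = "one", snp_ids = co$variants$id[1]),
                         co, spec, params)
  expect_equal(res1$emp_p,
               oracle_set_test_exact(y, g[, 1, drop = FALSE],
                                     matrix(1, 1, 1), 0.5, 0.5),
               tolerance = 1e-12)
})

test_that("wald_refit agrees with a glm-based brute force with a covariate", {
  set.seed(5)
  n <- 8
  g <- matrix(rbinom(n * 2, 2, 0.4), n, 2)
  age <- c(30, 45, 52, 38, 61, 44, 50, 35)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0)
  co <- make_test_cohort(g)
  co$samples$phenotyped <- TRUE
  co$samples$hypertensive <- y == 1
  co$samples$age <- age
  spec <- model_spec("HTN", covariates = "age")
  params <- set_test_params(p_cutoff = 0.9, perm_method = "exhaustive",
                            stat_mode = "wald_refit", seed = 1)
  res <- set_based_test(list(name = "t", snp_ids = co$variants$id), co,
                        spec, params)
  # independent brute force over all labelings with per-labeling glm fits
  r2 <- ld_r2_matrix(g)
  stat_cut <- qchisq(0.9, 1, lower.tail = FALSE)
  wstat <- function(yy, gj) {
    cf <- summary(suppressWarnings(
      glm(yy ~ gj + age, family = binomial())))$coefficients
    if (!"gj" %in% rownames(cf)) return(0)
    (cf["gj", 1] / cf["gj", 2])^2
  }
  set_stat <- function(yy) {
    st <- apply(g, 2, function(gj)
      if (length(unique(gj)) < 2) 0 else wstat(yy, gj))
    sel <- oracle_greedy(st, r2, stat_cut, 0.5)
    if (length(sel)) mean(st[sel]) else 0
  }
  obs <- set_stat(y)
  labs <- combn(n, sum(y))
  stats <- apply(labs, 2, function(ci) {
    yy <- numeric(n); yy[ci] <- 1; set_stat(yy)
  })
  expect_equal(res$emp_p, mean(stats >= obs - 1e-12), tolerance = 1e-12)
})

test_that("a planted causal set outranks a matched null set", {
  wins <- 0
  for (r in 1:10) {
    sim <- simulate_cohort(simulation_spec(
      n_samples = 800,
      pathways = data.frame(name = c("CAUSAL", "NULL1"), n_genes = 2,
                            snps_per_gene = 5),
      causal_pathway = "CAUSAL", causal_snp_fraction = 0.5,
      effect_or_range = c(1.35, 1.35), seed = 500 + r))
    params <- set_test_params(n_perm = 500, seed = r,
                              stat_mode = "score_fast")
    pc <- set_based_test(sim$pathways$CAUSAL, sim$cohort,
                         model_spec("HTN"), params)
    pn <- set_based_test(sim$pathways$NULL1, sim$cohort,
                         model_spec("HTN"), params)
    if (pc$emp_p < pn$emp_p) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("null empirical p-values are uniform when selection never stops", {
  # with P_SNP cutoff 1 the selection is never empty and the empirical p is
  # an exchangeable rank: exactly uniform up to permutation-grid discreteness
  sim <- simulate_cohort(simulation_spec(
    n_samples = 300,
    pathways = data.frame(name = sprintf("PW%02d", 1:10), n_genes = 2,
                          snps_per_gene = 10),
    ld_block_size = 1, causal_pathway = NA, missing_rate = 0, seed = 61))
  snps <- sim$cohort$variants$id
  sets <- lapply(seq_along(snps), function(i)
    list(name = paste0("S", i), snp_ids = snps[i]))
  names(sets) <- vapply(sets, `[[`, "", "name")
  params <- set_test_params(p_cutoff = 1, n_perm = 500, seed = 62,
                            stat_mode = "score_fast")
  res <- run_level(sim$cohort, sets, params, outcomes = "HTN",
                   level = "gene")
  ks <- suppressWarnings(stats::ks.test(res$emp_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("score_fast and wald_refit rank sets concordantly", {
  # 20 sets with graded planted effects; ranking by observed set statistic
  sim <- simulate_cohort(simulation_spec(
    n_samples = 400,
    pathways = data.frame(name = sprintf("PW%02d", 1:20), n_genes = 1,
                          snps_per_gene = 3),
    causal_pathway = NA, missing_rate = 0, seed = 71))
  co <- sim$cohort
  # plant graded effects directly through the phenotype
  set.seed(72)
  eff <- seq(0, 0.6, length.out = 20)
  eta <- numeric(n_samples(co))
  for (k in 1:20) {
    gk <- co$genotypes[, sim$pathways[[k]]$snp_ids[1]]
    eta <- eta + eff[k] * ifelse(is.na(gk), 0, gk)
  }
  co$samples$hypertensive <- runif(length(eta)) < plogis(eta - mean(eta))
  stat_of <- function(mode) {
    params <- set_test_params(p_cutoff = 1, seed = 1, stat_mode = mode)
    vapply(sim$pathways, function(pd) {
      eng <- pathscan:::.settest_engine(co, model_spec("HTN"), params,
                                        pd$snp_ids, observed_only = TRUE)
      res <- pathscan:::.set_result(eng, pd$name, "pathway", params)
      res$set_stat
    }, numeric(1))
  }
  s_fast <- stat_of("score_fast")
  s_wald <- stat_of("wald_refit")
  expect_gte(cor(s_fast, s_wald, method = "spearman"), 0.95)
})

test_that("sensitivity grid: labels, monotone selection on an LD-free toy,
          empty grid", {
  sim <- simulate_cohort(simulation_spec(
    n_samples = 500,
    pathways = data.frame(name = "PW01", n_genes = 2, snps_per_gene = 10),
    ld_block_size = 1, causal_pathway = "PW01", causal_snp_fraction = 0.4,
    effect_or_range = c(1.4, 1.5), missing_rate = 0, seed = 81))
  params <- set_test_params(n_perm = 200, seed = 82,
                            stat_mode = "score_fast")
  tab <- sensitivity_grid(sim$pathways$PW01, sim$cohort, params,
                          outcomes = "HTN")
  expect_equal(tab$condition, c("Default", "Strict", "Loose"))
  expect_equal(tab$r2, c(0.5, 0.1, 0.8))
  expect_equal(tab$p_cutoff, c(0.05, 0.01, 0.05))
  # LD-free toy: tightening the p cutoff can only shrink the selection
  expect_lte(tab$n_sig[tab$condition == "Strict"],
             tab$n_sig[tab$condition == "Default"])
  empty <- sensitivity_grid(sim$pathways$PW01, sim$cohort, params,
                            grid = data.frame(condition = character(0),
                                              r2 = numeric(0),
                                              p_cutoff = numeric(0)),
                            outcomes = "HTN")
  expect_equal(nrow(empty), 0)
})

test_that("bonferroni_cutoff is exact division with display rounding", {
  expect_equal(bonferroni_cutoff(0.05, 1), 0.05)
  expect_equal(bonferroni_cutoff(0.05, 28), 0.05 / 28)
  expect_error(bonferroni_cutoff(0.05, 0))
  expect_equal(format_cutoff(bonferroni_cutoff(0.05, 28), 1), 0.002)
  expect_equal(format_p(c(1, 0.28, 0.0009412)), c("1.00", "0.28", "0.00094"))
  expect_equal(format_p(1e-6, n_perm = 999), "0.0010")
})

test_that("empirical p bounds and determinism", {
  sim <- small_sim(91, n = 150, n_pathways = 2, snps_per_gene = 5)
  params <- set_test_params(n_perm = 99, seed = 7, stat_mode = "score_fast")
  r1 <- run_level(sim$cohort, sim$pathways, params, outcomes = "HTN")
  r2 <- run_level(sim$cohort, sim$pathways, params, outcomes = "HTN")
  expect_identical(r1, r2)
  expect_true(all(r1$emp_p >= 1 / 100 & r1$emp_p <= 1))
  expect_true(all(r1$emp_p[r1$n_sig == 0] == 1))
})
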