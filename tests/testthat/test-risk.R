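toy_assoc <- function() {
  data.frame(snp = c("s1", "s2", "s3", "s4"),
             effect = c(log(1.42), log(0.57), -2.10, 0),
             stringsAsFactors = FALSE)
}

test_that("direction assignment follows the sign of the effect", {
  m <- build_risk_model(toy_assoc(), c("s1", "s2", "s3"))
  expect_equal(m$direction, c("risk", "protective", "protective"))
  expect_warning(m0 <- build_risk_model(toy_assoc(), c("s1", "s4")),
                 "null effect")
  expect_equal(m0$snp, "s1")
  expect_error(build_risk_model(toy_assoc(), character(0)), "empty")
  expect_error(build_risk_model(toy_assoc(), "nope"), "missing")
})

test_that("score counts unfavorable alleles over non-missing model SNPs", {
  g <- rbind(c(1L, 1L, 2L),        # worked example
             c(2L, 0L, 2L),        # all unfavorable
             c(0L, 2L, 0L),        # all favorable
             c(1L, NA, 2L),        # missing drops from r and n
             c(NA, NA, NA))        # all missing -> NA score
  co <- make_test_cohort(g)
  model <- data.frame(snp = c("s001", "s002", "s003"),
                      direction = c("risk", "protective", "risk"),
                      source_effect = c(0.3, -0.5, 0.4))
  sc <- score_samples(co, model)
  expect_equal(sc$r, c(1 + (2 - 1) + 2, 6, 0, 3, 0))
  expect_equal(sc$n, c(6, 6, 6, 4, 0))
  expect_equal(sc$score, c(4 / 6, 1, 0, 3 / 4, NA))
  expect_true(all(sc$score >= 0 & sc$score <= 1, na.rm = TRUE))
})

test_that("score is order-invariant, duplication-invariant, and flips", {
  sim <- small_sim(41, n = 120, snps_per_gene = 6)
  a <- assoc_scan(sim$cohort, model_spec("HTN"))
  snps <- a$snp[a$effect != 0 & !is.na(a$effect)][1:8]
  model <- build_risk_model(a, snps)
  sc <- score_samples(sim$cohort, model)
  sc_shuf <- score_samples(sim$cohort, model[sample(nrow(model)), ])
  expect_equal(sc$score, sc_shuf$score)

  dbl <- subset_cohort(sim$cohort,
                       samples = rep(seq_len(n_samples(sim$cohort)), 2))
  dbl$samples$id <- make.unique(dbl$samples$id)
  sc_dbl <- score_samples(dbl, model)
  expect_equal(sc_dbl$score, rep(sc$score, 2))

  flipped <- model
  flipped$direction <- ifelse(model$direction == "risk", "protective",
                              "risk")
  sc_flip <- score_samples(sim$cohort, flipped)
  expect_equal(sc_flip$score, 1 - sc$score)
})

test_that("quintile assignment: equal split, boundary to lower, degeneracy", {
  set.seed(1)
  samples <- data.frame(id = sprintf("I%03d", 1:100), phenotyped = TRUE,
                        hypertensive = rep(c(TRUE, FALSE), 50))
  scores <- data.frame(id = samples$id, r = 0, n = 2,
                       score = sample(seq(0.005, 1, by = 0.005), 100))
  qm <- quintile_model(scores, samples,
                       model_spec("HTN", covariates = character(0)))
  expect_equal(unname(qm$n_per_quintile), rep(20L, 5))
  # with n = 101 the 20th percentile is an observed value: boundary sample
  # lands in the lower quintile
  s101 <- data.frame(id = 1:101, phenotyped = TRUE,
                     hypertensive = rep_len(c(TRUE, FALSE), 101))
  q101 <- quintile_model(data.frame(score = (0:100) / 100), s101,
                         model_spec("HTN", covariates = character(0)))
  expect_equal(unname(q101$breaks[1]), 0.20)
  expect_equal(unname(q101$quintile[21]), 1L)
  expect_equal(unname(q101$quintile[22]), 2L)
  expect_error(quintile_model(
    data.frame(score = rep(c(0.1, 0.2), 50)), samples), "distinct")
  expect_error(quintile_model(
    data.frame(score = c(rep(0.5, 96), 0.1, 0.2, 0.3, 0.4, 0.6)),
    data.frame(id = 1:101, phenotyped = TRUE, hypertensive = TRUE)),
    "degenerate|quintile")
})

test_that("quintile model is calibrated under the null and recovers a trend", {
  null_cover <- 0; monotone <- 0
  for (r in 1:20) {
    set.seed(300 + r)
    n <- 600
    score <- runif(n)
    s <- data.frame(id = seq_len(n), phenotyped = TRUE,
                    sex = sample(c("male", "female"), n, TRUE),
                    age = runif(n, 20, 80), bmi = rnorm(n, 24, 4))
    # null: outcome independent of score
    s$hypertensive <- runif(n) < 0.5
    qm <- quintile_model(data.frame(score = score), s, model_spec("HTN"))
    ci <- qm$estimates[2:5, ]
    if (all(ci$ci_lo <= 1 & 1 <= ci$ci_hi)) null_cover <- null_cover + 1
    # linear score effect on a continuous outcome
    s$sbp_adj <- 120 + 25 * score + rnorm(n, 0, 8)
    qs <- quintile_model(data.frame(score = score), s, model_spec("SBP"))
    est <- qs$estimates$estimate[2:5]
    if (all(diff(est) >= 0)) monotone <- monotone + 1
  }
  expect_gte(null_cover, 18)
  expect_gte(monotone, 18)
})

test_that("planted causal pathway yields an increasing quintile risk curve", {
  sim <- simulate_cohort(simulation_spec(
    n_samples = 1614,
    pathways = data.frame(name = sprintf("PW%02d", 1:4), n_genes = 2,
                          snps_per_gene = 10),
    causal_pathway = "PW01", causal_snp_fraction = 0.5,
    effect_or_range = c(1.25, 1.4), seed = 55))
  a <- assoc_scan(sim$cohort, model_spec("HTN"))
  sel <- observed_selection(sim$pathways$PW01, sim$cohort,
                            model_spec("HTN"),
                            set_test_params(seed = 1,
                                            stat_mode = "score_fast"))
  expect_gt(length(sel), 0)
  model <- build_risk_model(a, sel)
  sc <- score_samples(sim$cohort, model)
  qm <- quintile_model(sc, sim$cohort$samples, model_spec("HTN"))
  top <- qm$estimates[5, ]
  expect_gt(top$estimate, 1)
  expect_gt(top$ci_lo, 1)     # top-vs-bottom quintile OR excludes the null
})
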