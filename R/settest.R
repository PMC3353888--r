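#' Set-based test parameters
#'
#' Defaults are the analysis defaults: LD pruning at r^2 > 0.5, per-SNP
#' selection cutoff P_SNP <= 0.05, 10,000 phenotype permutations.
#'
#' @param r2_threshold LD pruning threshold in \[0, 1\]: after a SNP is
#'   selected, remaining SNPs with squared dosage correlation strictly above
#'   this are eliminated.
#' @param p_cutoff per-SNP p-value cutoff ending the greedy selection.
#' @param n_perm number of permuted datasets.
#' @param seed RNG seed for the permutations (required for reproducibility).
#' @param stat_mode `"auto"`, `"score_fast"` (score statistics from the
#'   null-covariate model, used for the observed and all permuted datasets;
#'   missing dosages mean-imputed) or `"wald_refit"` (full per-SNP Wald
#'   refits, complete-case; the reference mode).  `"auto"` picks
#'   `score_fast` when the run needs more than 1e5 SNP fits.
#' @param perm_method `"sample"` (Monte-Carlo) or `"exhaustive"` (enumerate
#'   all distinct case/control labelings; binary outcome, small n only).
#' @return a `set_test_params` list.
#' @export
set_test_params <- function(r2_threshold = 0.5, p_cutoff = 0.05,
                            n_perm = 10000L, seed = 1L,
                            stat_mode = c("auto", "score_fast", "wald_refit"),
                            perm_method = c("sample", "exhaustive")) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1,
            p_cutoff > 0, p_cutoff <= 1, n_perm >= 1)
  structure(list(r2_threshold = r2_threshold, p_cutoff = p_cutoff,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 stat_mode = match.arg(stat_mode),
                 perm_method = match.arg(perm_method)),
            class = "set_test_params")
}

#' Pairwise LD r-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise-complete
#' samples.  If either vector is constant on that subset the correlation is
#' undefined; 0 is returned so that an uninformative SNP can never justify
#' pruning another.
#'
#' @param d1,d2 dosage vectors.
#' @return r^2 in \[0, 1\].
#' @export
pairwise_r2 <- function(d1, d2) {
  ok <- !is.na(d1) & !is.na(d2)
  if (sum(ok) < 2) return(0)
  if (var(d1[ok]) == 0 || var(d2[ok]) == 0) return(0)
  cor(d1[ok], d2[ok])^2
}

#' LD r-squared matrix for a SNP set
#'
#' @param g dosage matrix (samples x SNPs).
#' @return symmetric r^2 matrix with unit diagonal; undefined entries are 0.
#' @export
ld_r2_matrix <- function(g) {
  r <- suppressWarnings(cor(g, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Greedy LD-pruned SNP selection
#'
#' The iterative selection at the heart of the set-based test: pick the
#' remaining SNP with the smallest p-value; if it does not meet `p_cutoff`,
#' stop; otherwise keep it and eliminate all remaining SNPs whose r^2 with
#' it exceeds `r2_threshold`; repeat.  Ties in p are broken by input order,
#' which callers arrange to be (chromosome, position) order.
#'
#' @param pvals per-SNP p-values (NA treated as 1).
#' @param r2 r^2 matrix among the SNPs ([ld_r2_matrix()]).
#' @param p_cutoff,r2_threshold see [set_test_params()].
#' @return integer indices of selected SNPs, in selection order.
#' @export
greedy_select <- function(pvals, r2, p_cutoff = 0.05, r2_threshold = 0.5) {
  stats <- qchisq(ifelse(is.na(pvals), 1, pvals), df = 1, lower.tail = FALSE)
  .greedy(stats, r2, qchisq(p_cutoff, 1, lower.tail = FALSE), r2_threshold)
}

# stat-scale greedy: select while max stat >= stat_cut (<=> p <= p_cutoff)
.greedy <- function(stats, r2, stat_cut, r2_threshold) {
  alive <- !is.na(stats)
  sel <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    best <- cand[which.max(stats[cand])]
    if (stats[best] < stat_cut) break
    sel <- c(sel, best)
    alive[best] <- FALSE
    alive[alive & r2[, best] > r2_threshold] <- FALSE
  }
  sel
}

# ---------------------------------------------------------------------------
# permutation statistic engine

.score_prep <- function(y, x, g, family) {
  g[is.na(g)] <- matrix(colMeans(g, na.rm = TRUE), nrow(g), ncol(g),
                        byrow = TRUE)[is.na(g)]
  if (family == "gaussian") {
    qx <- qr(x)
    gt <- g - x %*% qr.coef(qx, g)       # residualized dosages, X' gt = 0
    list(family = family, x = x, qx = qx, gt = gt,
         gss = colSums(gt^2), n = nrow(x), k = ncol(x))
  } else {
    list(family = family, x = x, g = g, n = nrow(x), k = ncol(x))
  }
}

.score_stats <- function(prep, yp) {
  if (prep$family == "gaussian") {
    res <- yp - prep$x %*% qr.coef(prep$qx, yp)
    sigma2 <- sum(res^2) / (prep$n - prep$k)
    u <- crossprod(prep$gt, yp)          # == gt' res since X' gt = 0
    stat <- as.numeric(u)^2 / (sigma2 * prep$gss)
  } else {
    fit <- suppressWarnings(glm.fit(prep$x, yp, family = binomial()))
    ph <- fit$fitted.values
    w <- ph * (1 - ph)
    u <- crossprod(prep$g, yp - ph)
    xw <- prep$x * w
    m <- crossprod(prep$x, xw)
    b <- crossprod(prep$g, xw)
    v <- colSums(prep$g^2 * w) - rowSums((b %*% solve(m)) * b)
    stat <- as.numeric(u)^2 / v
  }
  stat[!is.finite(stat) | stat < 0] <- 0
  stat
}

.wald_stats <- function(yp, x, g, family) {
  vapply(seq_len(ncol(g)), function(j) {
    gj <- g[, j]
    ok <- !is.na(gj)
    if (length(unique(gj[ok])) < 2) return(0)
    dat <- data.frame(.y = yp[ok], dosage = gj[ok],
                      x[ok, -1, drop = FALSE], check.names = FALSE)
    cf <- if (family == "binomial")
      summary(suppressWarnings(glm(.y ~ ., data = dat,
                                   family = binomial())))$coefficients
    else summary(lm(.y ~ ., data = dat))$coefficients
    row <- match("dosage", rownames(cf))
    if (is.na(row) || is.na(cf[row, 2]) || cf[row, 2] == 0) return(0)
    (cf[row, 1] / cf[row, 2])^2
  }, numeric(1))
}

# Observed + permuted 1-df statistics for a SNP panel.  Permutation swaps
# the phenotype vector over individuals (case/control label swapping, or
# its continuous-trait analogue); covariate rows stay with individuals.
# LD is computed once on the observed genotypes and never re-permuted.
.settest_engine <- function(cohort, spec, params, snp_ids,
                            observed_only = FALSE) {
  v <- cohort$variants
  vi <- match(snp_ids, v$id)
  if (anyNA(vi)) stop("set SNPs absent from genotype matrix: ",
                      paste(snp_ids[is.na(vi)], collapse = ", "))
  ord <- order(.chrom_rank(v$chrom[vi]), v$pos[vi])
  vi <- vi[ord]
  snp_ids <- snp_ids[ord]
  mf <- .model_frame(cohort$samples, spec)
  idx <- which(mf$ok)
  y <- mf$y[idx]
  x <- mf$x[idx, , drop = FALSE]
  g <- cohort$genotypes[idx, vi, drop = FALSE]
  storage.mode(g) <- "double"
  family <- if (spec$outcome == "HTN") "binomial" else "gaussian"

  mode <- params$stat_mode
  if (mode == "auto")
    mode <- if ((params$n_perm + 1) * length(vi) > 1e5) "score_fast"
            else "wald_refit"

  perms <- NULL
  exhaustive <- params$perm_method == "exhaustive"
  if (exhaustive) {
    if (family != "binomial")
      stop("exhaustive enumeration implemented for the binary outcome only")
    ncase <- sum(y == 1)
    if (choose(length(y), ncase) > 1e5)
      stop("too many distinct labelings for exhaustive enumeration")
    cases <- combn(length(y), ncase)
    perms <- apply(cases, 2, function(ci) {
      yy <- numeric(length(y)); yy[ci] <- 1; yy
    })                                   # n x n_labelings
  }

  if (mode == "score_fast") {
    prep <- .score_prep(y, x, g, family)
    stat_fun <- function(yp) .score_stats(prep, yp)
  } else {
    stat_fun <- function(yp) .wald_stats(yp, x, g, family)
  }
  obs <- stat_fun(y)

  if (observed_only) {
    n_perm <- 0L
    perm_stats <- matrix(0, 0, length(vi))
  } else if (exhaustive) {
    n_perm <- ncol(perms)
    perm_stats <- t(apply(perms, 2, stat_fun))
    dim(perm_stats) <- c(n_perm, length(vi))
  } else {
    n_perm <- params$n_perm
    perm_stats <- matrix(0, n_perm, length(vi))
    set.seed(params$seed)
    for (b in seq_len(n_perm))
      perm_stats[b, ] <- stat_fun(y[sample.int(length(y))])
  }
  list(snp_ids = snp_ids, obs = obs, perm_stats = perm_stats,
       n_perm = n_perm, exhaustive = exhaustive,
       r2 = ld_r2_matrix(g), stat_mode = mode, n_samples = length(y))
}

# greedy selection + empirical p for one set, given engine output
.set_result <- function(eng, set_name, level, params,
                        members = seq_along(eng$snp_ids)) {
  stat_cut <- qchisq(params$p_cutoff, 1, lower.tail = FALSE)
  r2 <- eng$r2[members, members, drop = FALSE]
  sel <- .greedy(eng$obs[members], r2, stat_cut, params$r2_threshold)
  obs_stat <- if (length(sel)) mean(eng$obs[members][sel]) else 0
  perm_stat <- if (nrow(eng$perm_stats) == 0) numeric(0) else
    apply(eng$perm_stats[, members, drop = FALSE], 1,
          function(s) {
            ps <- .greedy(s, r2, stat_cut, params$r2_threshold)
            if (length(ps)) mean(s[ps]) else 0
          })
  hits <- sum(perm_stat >= obs_stat - 1e-12)
  emp_p <- if (eng$exhaustive) hits / eng$n_perm
           else (1 + hits) / (eng$n_perm + 1)
  structure(list(set_name = set_name, level = level,
                 n_snps = length(members),
                 selected = eng$snp_ids[members][sel],
                 n_sig = length(sel), set_stat = obs_stat,
                 n_perm = eng$n_perm, emp_p = emp_p,
                 stat_mode = eng$stat_mode),
            class = "set_test_result")
}

#' @export
print.set_test_result <- function(x, ...) {
  cat(sprintf("%s-level set test: %s\n", x$level, x$set_name))
  cat(sprintf("  SNPs %d, N Sig %d, set stat %.3f, empirical p %s (%d perms)\n",
              x$n_snps, x$n_sig, x$set_stat, format_p(x$emp_p), x$n_perm))
  invisible(x)
}

#' Set-based permutation test for one SNP set
#'
#' The observed dataset is analyzed per SNP, the greedy LD-pruned selection
#' ([greedy_select()]) is applied, and the set statistic is the mean 1-df
#' chi-square statistic of the selected SNPs (0 when none is selected).
#' Permuted datasets are created by swapping the phenotype labels across
#' individuals (covariates stay attached to their individuals) and the whole
#' per-SNP-analysis + selection procedure is re-run on each.  The empirical
#' p-value is `(1 + #{permuted set stat >= observed}) / (n_perm + 1)`; with
#' `perm_method = "exhaustive"` it is the exact proportion over all distinct
#' case/control labelings.  A set with zero SNPs, or in which no SNP meets
#' the selection cutoff, has `n_sig = 0` and empirical p 1.00.
#'
#' @param set_def a `pathway_def` from [build_pathways()], or a character
#'   vector of SNP ids, or a list with `name` and `snp_ids`.
#' @param cohort a QC'd `cohort`.
#' @param spec a [model_spec()] choosing the outcome.
#' @param params a [set_test_params()].
#' @param level label stored in the result (`"pathway"` or `"gene"`).
#' @return a `set_test_result`: `set_name`, `level`, `n_snps`, `selected`,
#'   `n_sig`, `set_stat`, `n_perm`, `emp_p`.
#' @export
set_based_test <- function(set_def, cohort, spec = model_spec("HTN"),
                           params = set_test_params(), level = "pathway") {
  if (is.character(set_def)) set_def <- list(name = "set", snp_ids = set_def)
  if (length(set_def$snp_ids) == 0)
    return(structure(list(set_name = set_def$name, level = level,
                          n_snps = 0L, selected = character(0), n_sig = 0L,
                          set_stat = 0, n_perm = 0L, emp_p = 1,
                          stat_mode = params$stat_mode),
                     class = "set_test_result"))
  eng <- .settest_engine(cohort, spec, params, set_def$snp_ids)
  .set_result(eng, set_def$name, level, params)
}

#' Observed greedy selection for a set (no permutations)
#'
#' The LD-pruned selection the set-based test would make on the observed
#' data, without running any permutation; used e.g. to define the risk
#' model's SNP list.
#'
#' @inheritParams set_based_test
#' @return character vector of selected SNP ids, in selection order.
#' @export
observed_selection <- function(set_def, cohort, spec = model_spec("HTN"),
                               params = set_test_params()) {
  if (is.character(set_def)) set_def <- list(name = "set", snp_ids = set_def)
  if (!length(set_def$snp_ids)) return(character(0))
  eng <- .settest_engine(cohort, spec, params, set_def$snp_ids,
                         observed_only = TRUE)
  res <- .set_result(eng, set_def$name, "pathway", params)
  res$selected
}

#' Run set-based tests for many sets and outcomes
#'
#' Shares one permutation stream (and one per-permutation statistic scan
#' over the union of all member SNPs) across all sets of a level, exactly as
#' the per-set procedure would but without redundant refits.  For each set
#' the most significant selected SNP's Wald effect (odds ratio for HTN,
#' beta in mmHg otherwise) is reported, the gene-table convention; it is NA
#' when nothing is selected.
#'
#' @param cohort a QC'd `cohort`.
#' @param sets list of `pathway_def`-like sets (see [set_based_test()]).
#' @param params a [set_test_params()].
#' @param outcomes outcomes to test.
#' @param level `"pathway"` or `"gene"`.
#' @return data.frame, one row per set x outcome: `set, level, n_snps,
#'   outcome, n_sig, set_stat, emp_p, n_perm, top_snp, top_effect, top_p`.
#' @export
run_level <- function(cohort, sets, params = set_test_params(),
                      outcomes = c("HTN", "DBP", "SBP"),
                      level = c("pathway", "gene")) {
  level <- match.arg(level)
  if (is.null(names(sets)))
    names(sets) <- vapply(sets, `[[`, "", "name")
  all_snps <- unique(unlist(lapply(sets, `[[`, "snp_ids"),
                            use.names = FALSE))
  out <- list()
  for (oc in outcomes) {
    spec <- model_spec(oc)
    eng <- if (length(all_snps))
      .settest_engine(cohort, spec, params, all_snps) else NULL
    wald <- NULL                         # lazy per-outcome Wald scan cache
    for (sn in names(sets)) {
      snps <- sets[[sn]]$snp_ids
      if (length(snps) == 0) {
        res <- set_based_test(sets[[sn]], cohort, spec, params, level)
      } else {
        res <- .set_result(eng, sn, level, params,
                           members = match(snps, eng$snp_ids))
      }
      top_snp <- if (res$n_sig > 0) res$selected[1] else NA_character_
      top_effect <- top_p <- NA_real_
      if (!is.na(top_snp)) {
        a <- snp_association(
          cohort$genotypes[, match(top_snp, cohort$variants$id)],
          cohort$samples, spec, top_snp)
        top_effect <- if (oc == "HTN") a$or else a$effect
        top_p <- a$p
      }
      out[[length(out) + 1]] <- data.frame(
        set = sn, level = level, n_snps = res$n_snps, outcome = oc,
        n_sig = res$n_sig, set_stat = res$set_stat, emp_p = res$emp_p,
        n_perm = res$n_perm, top_snp = top_snp, top_effect = top_effect,
        top_p = top_p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sensitivity grid over pruning and selection cutoffs
#'
#' Re-evaluates one set's empirical p-value over a grid of
#' (r^2 threshold, P_SNP cutoff) conditions, the default grid being the
#' published Default (0.5, 0.05) / Strict (0.1, 0.01) / Loose (0.8, 0.05)
#' rows.  The permutation stream (same seed) is shared across cells, so
#' cells differ only in selection behaviour.
#'
#' @param set_def the set (see [set_based_test()]).
#' @param cohort a QC'd `cohort`.
#' @param params baseline [set_test_params()] (seed, n_perm, stat mode).
#' @param grid data.frame with columns `condition, r2, p_cutoff`.
#' @param outcomes outcomes to evaluate.
#' @return data.frame `outcome, condition, r2, p_cutoff, n_sig, emp_p`.
#' @export
sensitivity_grid <- function(set_def, cohort, params = set_test_params(),
                             grid = data.frame(
                               condition = c("Default", "Strict", "Loose"),
                               r2 = c(0.5, 0.1, 0.8),
                               p_cutoff = c(0.05, 0.01, 0.05)),
                             outcomes = c("HTN", "SBP", "DBP")) {
  if (nrow(grid) == 0)
    return(data.frame(outcome = character(0), condition = character(0),
                      r2 = numeric(0), p_cutoff = numeric(0),
                      n_sig = integer(0), emp_p = numeric(0)))
  if (is.character(set_def)) set_def <- list(name = "set", snp_ids = set_def)
  out <- list()
  for (oc in outcomes) {
    spec <- model_spec(oc)
    eng <- .settest_engine(cohort, spec, params, set_def$snp_ids)
    for (i in seq_len(nrow(grid))) {
      pi <- params
      pi$r2_threshold <- grid$r2[i]
      pi$p_cutoff <- grid$p_cutoff[i]
      res <- .set_result(eng, set_def$name, "pathway", pi)
      out[[length(out) + 1]] <- data.frame(
        outcome = oc, condition = grid$condition[i], r2 = grid$r2[i],
        p_cutoff = grid$p_cutoff[i], n_sig = res$n_sig, emp_p = res$emp_p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Bonferroni significance cutoff
#'
#' `alpha / m`, exact.  The study's family sizes give 0.05/28 pathways =
#' 0.002 (1 s.f.), 0.05/101 genes = 0.0005, 0.05/4349 SNPs = 1.15e-5.
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return exact threshold.
#' @export
bonferroni_cutoff <- function(alpha = 0.05, m) {
  stopifnot(m >= 1)
  alpha / m
}

#' Display helpers for p-values and cutoffs
#'
#' `format_cutoff` rounds a Bonferroni cutoff to `sig_figs` significant
#' figures for display.  `format_p` renders a permutation p-value to two
#' significant figures, never below the resolution `1/(n_perm + 1)`, with
#' exact ones printed "1.00".
#'
#' @param x numeric value(s).
#' @param sig_figs significant figures.
#' @param n_perm permutation count used for the floor (optional).
#' @return character vector.
#' @export
format_cutoff <- function(x, sig_figs = 1) signif(x, sig_figs)

#' @rdname format_cutoff
#' @export
format_p <- function(x, n_perm = NULL) {
  if (!is.null(n_perm)) x <- pmax(x, 1 / (n_perm + 1))
  vapply(x, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p >= 0.995) return("1.00")
    formatC(signif(p, 2), format = "fg", flag = "#", digits = 2)
  }, character(1))
}
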