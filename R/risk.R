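#' Build an unfavorable-allele risk model
#'
#' For each selected SNP the unfavorable allele is the minor allele when
#' the association effect is risk-increasing (OR > 1 for the binary
#' outcome, beta > 0 for continuous BP) and the major allele when it is
#' protective (OR < 1 / beta < 0).  SNPs with an exactly null effect carry
#' no direction and are dropped with a warning.
#'
#' @param assoc association results ([assoc_scan()] output) for one
#'   outcome.
#' @param selected SNP ids forming the model (typically the greedy-selected
#'   set from [set_based_test()] for that outcome).
#' @return data.frame `snp, direction ("risk"/"protective"), source_effect`.
#' @export
build_risk_model <- function(assoc, selected) {
  if (!length(selected)) stop("empty SNP selection for risk model")
  m <- match(selected, assoc$snp)
  if (anyNA(m)) stop("selected SNPs missing from association results: ",
                     paste(selected[is.na(m)], collapse = ", "))
  eff <- assoc$effect[m]
  if (anyNA(eff)) stop("selected SNP(s) without an effect estimate")
  null_eff <- eff == 0
  if (any(null_eff)) {
    warning("dropping SNP(s) with exactly null effect: ",
            paste(selected[null_eff], collapse = ", "))
    selected <- selected[!null_eff]; eff <- eff[!null_eff]
  }
  data.frame(snp = selected,
             direction = ifelse(eff > 0, "risk", "protective"),
             source_effect = eff, stringsAsFactors = FALSE)
}

#' Per-sample unfavorable-allele ratio score
#'
#' For each individual, `r_i` counts unfavorable alleles over the model
#' SNPs (the minor-allele dosage for risk SNPs, its complement for
#' protective SNPs) and `n_i` counts the total alleles contributing (2 per
#' non-missing autosomal or female-X SNP, 1 per non-missing male-X SNP);
#' the score is `r_i / n_i` in \[0, 1\].  Missing genotypes drop out of
#' both numerator and denominator; a sample missing every model SNP gets
#' `NA`.
#'
#' @param cohort a `cohort`.
#' @param model a [build_risk_model()] data.frame.
#' @return data.frame `id, r, n, score`.
#' @export
score_samples <- function(cohort, model) {
  vi <- match(model$snp, cohort$variants$id)
  if (anyNA(vi)) stop("model SNPs absent from cohort: ",
                      paste(model$snp[is.na(vi)], collapse = ", "))
  g <- cohort$genotypes[, vi, drop = FALSE]
  storage.mode(g) <- "double"
  copies <- .allele_copies(cohort)[, vi, drop = FALSE]
  prot <- model$direction == "protective"
  unf <- g
  unf[, prot] <- copies[, prot, drop = FALSE] - g[, prot, drop = FALSE]
  copies[is.na(g)] <- NA_real_
  r <- rowSums(unf, na.rm = TRUE)
  n_tot <- rowSums(copies, na.rm = TRUE)
  score <- ifelse(n_tot > 0, r / n_tot, NA_real_)
  data.frame(id = cohort$samples$id, r = r, n = n_tot, score = score,
             stringsAsFactors = FALSE)
}

#' Quintile risk-score regression
#'
#' Categorizes the risk score at its 20/40/60/80th percentiles (boundary
#' values fall in the lower quintile) and fits the adjusted regression of
#' the outcome on quintile indicators, the lowest quintile being the
#' reference: logistic for HTN (reporting OR with 95% Wald CI per
#' quintile) or linear for SBP/DBP (beta with SE).
#'
#' @param scores [score_samples()] output (rows aligned with `samples`).
#' @param samples prepared sample table.
#' @param spec a [model_spec()].
#' @return list with `quintile` (per-sample assignment), `breaks`, and
#'   `estimates`: data.frame `quintile, estimate, se, ci_lo, ci_hi, p`
#'   (estimate is OR or beta; reference row Q1 has estimate 1 or 0).
#' @export
quintile_model <- function(scores, samples, spec = model_spec("HTN")) {
  sc <- scores$score
  ok0 <- !is.na(sc)
  if (length(unique(sc[ok0])) < 5)
    stop("fewer than 5 distinct score values")
  br <- quantile(sc[ok0], c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  q <- findInterval(sc, br, left.open = TRUE) + 1L   # boundary -> lower
  q[!ok0] <- NA_integer_
  tab <- tabulate(q, 5)
  if (any(tab == 0))
    stop("degenerate quintiles (tied mass) at breaks ",
         paste(signif(br[which(tab == 0)], 4), collapse = ", "))
  mf <- .model_frame(samples, spec)
  ok <- mf$ok & !is.na(q)
  qf <- factor(q[ok], levels = 1:5)
  x <- cbind(stats::model.matrix(~qf)[, -1, drop = FALSE],
             mf$x[ok, -1, drop = FALSE])
  y <- mf$y[ok]
  logistic <- spec$outcome == "HTN"
  fit <- if (logistic) glm(y ~ x, family = binomial()) else lm(y ~ x)
  cf <- summary(fit)$coefficients
  rows <- paste0("xqf", 2:5)
  est <- cf[rows, 1]; se <- cf[rows, 2]
  z <- qnorm(0.975)
  p <- pchisq((est / se)^2, 1, lower.tail = FALSE)
  estimates <- data.frame(
    quintile = 1:5,
    estimate = if (logistic) c(1, exp(est)) else c(0, est),
    se = c(NA, se),
    ci_lo = if (logistic) c(NA, exp(est - z * se)) else c(NA, est - z * se),
    ci_hi = if (logistic) c(NA, exp(est + z * se)) else c(NA, est + z * se),
    p = c(NA, p))
  rownames(estimates) <- NULL
  list(quintile = q, breaks = br, n_per_quintile = tab,
       estimates = estimates, outcome = spec$outcome)
}
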