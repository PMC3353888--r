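#' Association model specification
#'
#' Fixes the per-SNP regression model: outcome (hypertension case status,
#' fit by logistic regression; SBP or DBP in mmHg, fit by linear regression
#' on medication-adjusted values), the additive minor-allele dosage coding,
#' and the covariate set sex, age, age-squared and BMI.
#'
#' @param outcome `"HTN"`, `"SBP"` or `"DBP"`.
#' @param covariates covariate columns of the sample table entering every
#'   model (`age2` is derived as `age^2`).
#' @param med_adjust_sbp,med_adjust_dbp mmHg added to treated individuals'
#'   SBP/DBP for the continuous-trait analyses.
#' @param center_age center age before squaring (numerical conditioning
#'   option; default off, i.e. the literal age and age-squared).
#' @return a `model_spec` list.
#' @export
model_spec <- function(outcome = c("HTN", "SBP", "DBP"),
                       covariates = c("sex", "age", "age2", "bmi"),
                       med_adjust_sbp = 15, med_adjust_dbp = 10,
                       center_age = FALSE) {
  outcome <- match.arg(outcome)
  structure(list(outcome = outcome, covariates = covariates,
                 med_adjust_sbp = med_adjust_sbp,
                 med_adjust_dbp = med_adjust_dbp,
                 center_age = center_age),
            class = "model_spec")
}

#' Body mass index
#'
#' @param weight_kg body weight in kg.
#' @param height_m height in meters (> 0).
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.na(height_m) & height_m <= 0)) stop("non-positive height")
  weight_kg / height_m^2
}

#' Hypertension case definition
#'
#' Hypertensive iff SBP >= 140 mmHg, DBP >= 90 mmHg, or on
#' antihypertensive medication at exam.
#'
#' @param sbp,dbp blood pressure in mmHg (raw, unadjusted).
#' @param on_med logical, on antihypertensive medication.
#' @return logical vector.
#' @export
classify_hypertension <- function(sbp, dbp, on_med) {
  sbp >= 140 | dbp >= 90 | on_med
}

#' Medication adjustment of blood pressure
#'
#' Adds fixed constants (+15 mmHg SBP, +10 mmHg DBP by default) to treated
#' individuals' pressures to approximate their untreated values; used only
#' for the continuous-trait analyses, never for the case definition.
#'
#' @param sbp,dbp raw pressures in mmHg.
#' @param on_med logical.
#' @param spec a [model_spec()] carrying the adjustment constants.
#' @return list with numeric vectors `sbp_adj`, `dbp_adj`.
#' @export
adjust_bp_for_medication <- function(sbp, dbp, on_med, spec = model_spec()) {
  add <- !is.na(on_med) & on_med
  list(sbp_adj = sbp + ifelse(add, spec$med_adjust_sbp, 0),
       dbp_adj = dbp + ifelse(add, spec$med_adjust_dbp, 0))
}

#' X-chromosome genotype coding
#'
#' Males are hemizygous: 1 if the minor allele is present, 0 otherwise; a
#' heterozygous male call is biologically invalid and treated as missing.
#' Females are coded 0/1/2 as on autosomes.
#'
#' @param sex `"male"`/`"female"`.
#' @param raw raw genotype code in 0/1/2 (minor-allele count).
#' @return dosage: males in \{0, 1\}, females in \{0, 1, 2\}.
#' @export
code_x_genotype <- function(sex, raw) {
  out <- raw
  male <- !is.na(sex) & sex == "male"
  out[male & !is.na(raw) & raw == 1] <- NA_integer_
  out[male & !is.na(out) & out == 2] <- 1L
  out
}

#' Derive phenotype fields of a sample table
#'
#' Computes BMI from weight/height (keeping any supplied `bmi` where
#' weight/height are absent), medication-adjusted SBP/DBP, and the
#' hypertension classification from the raw pressures and medication flag.
#'
#' @param samples data.frame with `id, sex, age, weight_kg, height_m, sbp,
#'   dbp, on_med` (or `sbp_raw`/`dbp_raw`).
#' @param spec a [model_spec()].
#' @return the sample table with `bmi`, `sbp_raw`, `dbp_raw`, `sbp_adj`,
#'   `dbp_adj`, `hypertensive` and `phenotyped` columns.
#' @export
prepare_samples <- function(samples, spec = model_spec()) {
  s <- samples
  if (!"sbp_raw" %in% names(s)) { s$sbp_raw <- s$sbp; s$sbp <- NULL }
  if (!"dbp_raw" %in% names(s)) { s$dbp_raw <- s$dbp; s$dbp <- NULL }
  bmi <- compute_bmi(s$weight_kg, s$height_m)
  if (!"bmi" %in% names(s)) s$bmi <- bmi
  else s$bmi <- ifelse(is.na(bmi), s$bmi, bmi)
  adj <- adjust_bp_for_medication(s$sbp_raw, s$dbp_raw, s$on_med, spec)
  s$sbp_adj <- adj$sbp_adj
  s$dbp_adj <- adj$dbp_adj
  s$hypertensive <- classify_hypertension(s$sbp_raw, s$dbp_raw, s$on_med)
  if (!"phenotyped" %in% names(s))
    s$phenotyped <- !is.na(s$sbp_raw) | !is.na(s$hypertensive)
  s
}

# outcome vector + covariate design matrix for the analysis samples
.model_frame <- function(samples, spec) {
  y <- switch(spec$outcome,
              HTN = as.numeric(samples$hypertensive),
              SBP = samples$sbp_adj,
              DBP = samples$dbp_adj)
  age <- if (isTRUE(spec$center_age)) samples$age - mean(samples$age,
                                                         na.rm = TRUE)
  else samples$age
  cov_pool <- list(sex = as.numeric(!is.na(samples$sex) &
                                      samples$sex == "male"),
                   age = age, age2 = age^2, bmi = samples$bmi)
  x <- matrix(1, nrow(samples), 1, dimnames = list(NULL, "(Intercept)"))
  if (length(spec$covariates))
    x <- cbind(x, do.call(cbind, cov_pool[spec$covariates]))
  ok <- !is.na(y) & complete.cases(x)
  if ("phenotyped" %in% names(samples)) ok <- ok & samples$phenotyped
  list(y = y, x = x, ok = ok)
}

#' Per-SNP additive association test
#'
#' Fits `outcome ~ dosage + sex + age + age^2 + BMI` by maximum-likelihood
#' logistic regression (HTN) or ordinary least squares (SBP/DBP on
#' medication-adjusted values), complete-case on the covariates and on the
#' SNP.  Reports the additive effect (log-odds or mmHg per minor allele),
#' its standard error, the 1-df Wald chi-square `(effect/se)^2`, and the
#' two-sided p-value from the chi-square(1) survival function.  SNPs
#' monomorphic among analyzed samples are flagged and assigned p = 1 (so
#' set sizes stay stable downstream); non-converged logistic fits
#' (separation) are flagged.
#'
#' @param dosages numeric dosage vector (minor-allele counts, NA = missing).
#' @param samples prepared sample table (see [prepare_samples()]).
#' @param spec a [model_spec()].
#' @param snp_id id echoed in the result.
#' @return one-row data.frame: `snp, model, outcome, n_used, effect, se,
#'   or, stat, p, converged, monomorphic`.
#' @export
snp_association <- function(dosages, samples, spec = model_spec("HTN"),
                            snp_id = NA_character_) {
  mf <- .model_frame(samples, spec)
  ok <- mf$ok & !is.na(dosages)
  y <- mf$y[ok]
  x <- cbind(dosages[ok], mf$x[ok, -1, drop = FALSE])
  colnames(x) <- c("dosage", colnames(mf$x)[-1])
  dat <- data.frame(.y = y, x, check.names = FALSE)
  model <- if (spec$outcome == "HTN") "logistic" else "linear"
  res <- data.frame(snp = snp_id, model = model, outcome = spec$outcome,
                    n_used = length(y), effect = NA_real_, se = NA_real_,
                    or = NA_real_, stat = 0, p = 1, converged = TRUE,
                    monomorphic = FALSE, stringsAsFactors = FALSE)
  if (length(unique(x[, "dosage"])) < 2) {
    res$monomorphic <- TRUE
    return(res)
  }
  if (model == "logistic") {
    fit <- suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
    res$converged <- isTRUE(fit$converged) &&
      all(abs(coef(fit)) < 20, na.rm = TRUE)   # crude separation guard
    cf <- summary(fit)$coefficients
  } else {
    fit <- lm(.y ~ ., data = dat)
    cf <- summary(fit)$coefficients
  }
  row <- match("dosage", rownames(cf))
  if (is.na(row) || is.na(cf[row, 2]) || cf[row, 2] == 0) {
    res$converged <- FALSE
    return(res)
  }
  res$effect <- cf[row, 1]
  res$se <- cf[row, 2]
  if (model == "logistic") res$or <- exp(res$effect)
  res$stat <- (res$effect / res$se)^2
  res$p <- pchisq(res$stat, df = 1, lower.tail = FALSE)
  res
}

#' Association scan over all SNPs
#'
#' Runs [snp_association()] for every variant, in deterministic
#' (chromosome, position) order.
#'
#' @param cohort a `cohort` (after QC).
#' @param spec a [model_spec()].
#' @return data.frame, one row per SNP, with `chrom` and `pos` columns
#'   prepended to the [snp_association()] fields.
#' @export
assoc_scan <- function(cohort, spec = model_spec("HTN")) {
  v <- cohort$variants
  ord <- order(.chrom_rank(v$chrom), v$pos)
  rows <- lapply(ord, function(j)
    snp_association(cohort$genotypes[, j], cohort$samples, spec,
                    snp_id = v$id[j]))
  out <- do.call(rbind, rows)
  cbind(out[, "snp", drop = FALSE],
        chrom = v$chrom[ord], pos = v$pos[ord],
        out[, setdiff(names(out), "snp")])
}

.chrom_rank <- function(chrom) {
  r <- suppressWarnings(as.integer(chrom))
  r[chrom == "X"] <- 23L
  r
}
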