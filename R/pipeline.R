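#' Run configuration
#'
#' A fully serializable description of one end-to-end analysis: either a
#' simulation spec or paths to cohort/gene/pathway inputs, the QC
#' thresholds, set-test parameters, sensitivity grid, and output directory.
#' A run is reproducible from config + seed alone.  Configs round-trip
#' through JSON ([read_run_config()]).
#'
#' @param out_dir output directory.
#' @param seed root seed (required; also seeds the permutations).
#' @param simulation a [simulation_spec()] or NULL.
#' @param genotype_path,genotype_format,phenotype_path,gene_path,pathway_path
#'   input files when not simulating.
#' @param qc a [qc_thresholds()].
#' @param set_params a [set_test_params()] (its seed is overridden by
#'   `seed`).
#' @param outcomes outcomes to analyze.
#' @param flank_bp gene flank in bp.
#' @param run_qc apply QC before analysis?
#' @param risk_outcome outcome whose selected SNPs feed the risk model.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed, simulation = NULL,
                       genotype_path = NULL, genotype_format = "plink_text",
                       phenotype_path = NULL, gene_path = NULL,
                       pathway_path = NULL, qc = qc_thresholds(),
                       set_params = set_test_params(),
                       outcomes = c("HTN", "DBP", "SBP"),
                       flank_bp = 20000L, run_qc = TRUE,
                       risk_outcome = "HTN") {
  if (missing(seed) || is.null(seed)) stop("run_config: a seed is required")
  set_params$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulation = simulation, genotype_path = genotype_path,
                 genotype_format = genotype_format,
                 phenotype_path = phenotype_path, gene_path = gene_path,
                 pathway_path = pathway_path, qc = qc,
                 set_params = set_params, outcomes = outcomes,
                 flank_bp = as.integer(flank_bp), run_qc = run_qc,
                 risk_outcome = risk_outcome),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON config file.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- if (!is.null(j$simulation)) {
    s <- j$simulation
    s$pathways <- as.data.frame(s$pathways)
    do.call(simulation_spec, s)
  }
  run_config(out_dir = j$out_dir, seed = j$seed, simulation = sim,
             genotype_path = j$genotype_path,
             genotype_format = j$genotype_format %||% "plink_text",
             phenotype_path = j$phenotype_path, gene_path = j$gene_path,
             pathway_path = j$pathway_path,
             qc = do.call(qc_thresholds, j$qc %||% list()),
             set_params = do.call(set_test_params,
                                  c(j$set_params %||% list(),
                                    list(seed = j$seed))),
             outcomes = j$outcomes %||% c("HTN", "DBP", "SBP"),
             flank_bp = j$flank_bp %||% 20000L,
             run_qc = j$run_qc %||% TRUE,
             risk_outcome = j$risk_outcome %||% "HTN")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full pathway-focused analysis
#'
#' Executes simulate/read -> QC -> per-SNP association per outcome ->
#' pathway-level set tests -> gene-level set tests within the top pathway
#' -> sensitivity grid on the top pathway -> risk score and quintile models
#' -> rendered tables, writing every stage's table under
#' `config$out_dir` plus a JSON manifest (package version, seed, parameter
#' echo).  Deterministic: two runs with the same config produce
#' byte-identical tables.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of in-memory results: `cohort`, `qc_report`,
#'   `assoc` (per outcome), `pathway_results`, `top_pathway`,
#'   `gene_results`, `sensitivity`, `risk`, `tables`.
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(config$out_dir, f),
                                    sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  if (!is.null(config$simulation)) {
    sim <- .stage("simulate", simulate_cohort(config$simulation,
                                              config$flank_bp))
    cohort <- sim$cohort; genes <- sim$genes; pathway_df <- sim$pathway_df
  } else {
    cohort <- .stage("read", read_cohort(config$genotype_path,
                                         config$phenotype_path,
                                         config$genotype_format))
    genes <- .stage("read", read_gene_intervals(config$gene_path))
    pathway_df <- .stage("read", read_pathway_defs(config$pathway_path))
  }
  message(sprintf("cohort: %d samples, %d SNPs", n_samples(cohort),
                  n_variants(cohort)))
  qc_report <- NULL
  if (isTRUE(config$run_qc)) {
    qcres <- .stage("qc", apply_qc(cohort, config$qc))
    cohort <- qcres$cohort
    qc_report <- qcres$report
    tsv(qc_report, "qc_report.tsv")
    message(sprintf("after QC: %d samples, %d SNPs", n_samples(cohort),
                    n_variants(cohort)))
  }
  gmap <- .stage("pathways", assign_snps_to_genes(cohort$variants, genes,
                                                  config$flank_bp))
  pathways <- .stage("pathways", build_pathways(pathway_df, gmap))

  assoc <- list()
  for (oc in config$outcomes) {
    assoc[[oc]] <- .stage(paste0("assoc_", oc),
                          assoc_scan(cohort, model_spec(oc)))
    tsv(assoc[[oc]][, c("snp", "chrom", "pos", "n_used", "effect", "se",
                        "or", "stat", "p")],
        sprintf("assoc_%s.tsv", tolower(oc)))
  }

  pres <- .stage("settest_pathway",
                 run_level(cohort, pathways, config$set_params,
                           config$outcomes, "pathway"))
  tsv(pres, "pathway_results.tsv")
  first_oc <- config$outcomes[1]
  p1 <- pres[pres$outcome == first_oc, ]
  top_pathway <- p1$set[order(p1$emp_p, -p1$set_stat)][1]
  message("top pathway (", first_oc, "): ", top_pathway)

  top_def <- pathways[[top_pathway]]
  gene_sets <- lapply(top_def$genes, function(g)
    list(name = g, snp_ids = gmap[[g]] %||% character(0)))
  names(gene_sets) <- top_def$genes
  gres <- .stage("settest_gene",
                 run_level(cohort, gene_sets, config$set_params,
                           config$outcomes, "gene"))
  tsv(gres, "gene_results.tsv")

  sens <- .stage("sensitivity",
                 sensitivity_grid(top_def, cohort, config$set_params,
                                  outcomes = config$outcomes))
  tsv(sens, "sensitivity.tsv")

  risk <- .stage("risk_score", {
    ro <- config$risk_outcome
    sel <- observed_selection(top_def, cohort, model_spec(ro),
                              config$set_params)
    if (length(sel) == 0) NULL else {
      model <- build_risk_model(assoc[[ro]], sel)
      scores <- score_samples(cohort, model)
      qm <- quintile_model(scores, cohort$samples, model_spec(ro))
      tsv(model, "risk_model.tsv")
      tsv(scores, "risk_scores.tsv")
      tsv(qm$estimates, sprintf("quintile_%s.tsv", tolower(ro)))
      list(model = model, scores = scores, quintile = qm)
    }
  })

  tables <- render_tables(list(pathway = pres, gene = gres,
                               sensitivity = sens,
                               risk = risk, n_pathways = length(pathways)))
  writeLines(tables$markdown, file.path(config$out_dir, "tables.md"))
  manifest <- list(package = "pathscan",
                   version = as.character(utils::packageVersion("pathscan")),
                   seed = config$seed,
                   n_samples = n_samples(cohort),
                   n_snps = n_variants(cohort),
                   n_pathways = length(pathways),
                   top_pathway = top_pathway,
                   set_params = unclass(config$set_params),
                   qc = if (!is.null(qc_report)) qc_report$removed,
                   outcomes = config$outcomes)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cohort = cohort, qc_report = qc_report, assoc = assoc,
                 pathway_results = pres, top_pathway = top_pathway,
                 gene_results = gres, sensitivity = sens, risk = risk,
                 tables = tables))
}

#' Render publication-style tables
#'
#' Produces the pathway association table (one row per set, `SNPs`,
#' `N Sig` and empirical p per outcome, sorted by the first outcome's
#' empirical p, Bonferroni-starred), the gene table for the top pathway
#' (adding the most significant selected SNP's OR/beta, `NA` when nothing
#' is selected), the sensitivity grid and the quintile estimates, as
#' data.frames plus a markdown rendering.  Every cell is recomputable from
#' the persisted stage outputs.
#'
#' @param results list with `pathway`, `gene`, `sensitivity`, `risk`
#'   ([run_all()] internals) and `n_pathways`.
#' @return list of data.frames (`pathway_table`, `gene_table`,
#'   `sensitivity_table`, `quintile_table`) plus `markdown` lines.
#' @export
render_tables <- function(results) {
  wide <- function(df, value_cols) {
    ocs <- unique(df$outcome)
    base <- unique(df[, c("set", "n_snps")])
    for (oc in ocs) {
      sub <- df[df$outcome == oc, ]
      m <- match(base$set, sub$set)
      for (vc in value_cols)
        base[[paste0(vc, "_", oc)]] <- sub[[vc]][m]
    }
    base
  }
  pw <- wide(results$pathway, c("n_sig", "emp_p"))
  first_oc <- unique(results$pathway$outcome)[1]
  pw <- pw[order(pw[[paste0("emp_p_", first_oc)]]), ]
  cutoff <- bonferroni_cutoff(0.05, max(1, results$n_pathways))
  nper <- results$pathway$n_perm[1]
  for (oc in unique(results$pathway$outcome)) {
    pcol <- paste0("emp_p_", oc)
    pw[[pcol]] <- paste0(format_p(pw[[pcol]], nper),
                         ifelse(pw[[pcol]] < cutoff, "*", ""))
  }
  ge <- NULL
  if (!is.null(results$gene)) {
    ge <- wide(results$gene, c("n_sig", "emp_p", "top_effect"))
    for (oc in unique(results$gene$outcome)) {
      ge[[paste0("emp_p_", oc)]] <-
        format_p(ge[[paste0("emp_p_", oc)]], nper)
      ec <- paste0("top_effect_", oc)
      ge[[ec]] <- ifelse(is.na(ge[[ec]]), "NA", sprintf("%.2f", ge[[ec]]))
    }
  }
  se <- results$sensitivity
  if (!is.null(se)) se$emp_p <- format_p(se$emp_p, nper)
  qt <- if (!is.null(results$risk)) results$risk$quintile$estimates
  md <- c("# Pathway association results", "",
          knit_md(pw), "",
          sprintf("`*` empirical p below the Bonferroni cutoff %s (0.05/%d).",
                  format(format_cutoff(cutoff)), results$n_pathways), "")
  if (!is.null(ge)) md <- c(md, "# Genes in the top pathway", "",
                            knit_md(ge), "")
  if (!is.null(se)) md <- c(md, "# Sensitivity to R2 and P_SNP cutoffs", "",
                            knit_md(se), "")
  if (!is.null(qt)) md <- c(md, "# Risk-score quintile model", "",
                            knit_md(qt), "")
  list(pathway_table = pw, gene_table = ge, sensitivity_table = se,
       quintile_table = qt, markdown = md)
}

# minimal markdown table renderer
knit_md <- function(df) {
  if (is.null(df) || !nrow(df)) return("(empty)")
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, format = "g", digits = 4)
    else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1) fmt <- matrix(fmt, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                     " |")))
}
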