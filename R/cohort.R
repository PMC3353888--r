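#' Construct a cohort object
#'
#' A `cohort` bundles the three core tables of a genetic association study:
#' the genotype dosage matrix, per-variant metadata, and per-sample
#' phenotypes/covariates.  Dosages count copies of the *coded* allele, which
#' after [orient_to_minor()] (applied by every reader and the simulator) is
#' the minor allele: 0/1/2 on autosomes and for females on X, 0/1 for
#' hemizygous males on X, `NA` for missing calls.
#'
#' @param genotypes integer matrix, samples x variants, with sample ids as
#'   rownames and variant ids as colnames.
#' @param variants data.frame with at least `id`, `chrom` (character; "1"
#'   .."22" or "X"), `pos` (1-based bp), `minor_allele`, `major_allele`.
#'   Columns `maf`, `missing_rate`, `hwe_p` are added by
#'   [annotate_variants()].
#' @param samples data.frame with at least `id`; phenotype columns (`sex`,
#'   `age`, `weight_kg`, `height_m`, `bmi`, `sbp_raw`, `dbp_raw`, `on_med`,
#'   `sbp_adj`, `dbp_adj`, `hypertensive`, `phenotyped`) as produced by
#'   [prepare_samples()].
#' @param validate validate invariants (unique ids, dosage ranges)?
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(genotypes, variants, samples, validate = TRUE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants$chrom <- as.character(variants$chrom)
  rownames(genotypes) <- samples$id
  colnames(genotypes) <- variants$id
  obj <- structure(list(genotypes = genotypes, variants = variants,
                        samples = samples),
                   class = "cohort")
  if (validate) validate_cohort(obj)
  obj
}

#' @rdname new_cohort
#' @param x a `cohort`.
#' @export
validate_cohort <- function(x) {
  stopifnot(is.matrix(x$genotypes))
  if (anyDuplicated(x$samples$id))
    stop("duplicated sample ids: ",
         paste(unique(x$samples$id[duplicated(x$samples$id)]), collapse = ", "))
  if (anyDuplicated(x$variants$id))
    stop("duplicated variant ids: ",
         paste(unique(x$variants$id[duplicated(x$variants$id)]), collapse = ", "))
  stopifnot(nrow(x$genotypes) == nrow(x$samples),
            ncol(x$genotypes) == nrow(x$variants),
            all(x$variants$pos >= 1))
  g <- x$genotypes
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) stop("dosages outside {0,1,2,NA}")
  on_x <- x$variants$chrom == "X"
  if (any(on_x) && "sex" %in% names(x$samples)) {
    male <- which(!is.na(x$samples$sex) & x$samples$sex == "male")
    gx <- g[male, on_x, drop = FALSE]
    if (any(!is.na(gx) & gx == 2L))
      stop("male X dosages must be hemizygous (0/1)")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples x %d variants\n",
              nrow(x$samples), nrow(x$variants)))
  if ("phenotyped" %in% names(x$samples))
    cat(sprintf("  phenotyped: %d; hypertensive: %s\n",
                sum(x$samples$phenotyped),
                if ("hypertensive" %in% names(x$samples))
                  sum(x$samples$hypertensive, na.rm = TRUE) else "?"))
  chrs <- unique(x$variants$chrom)
  cat(sprintf("  chromosomes: %s\n",
              paste(head(chrs, 12), collapse = " ")))
  invisible(x)
}

#' Number of samples / variants
#' @param x a `cohort`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_variants <- function(x) nrow(x$variants)

# sex-aware per-variant maximum allele copies (2, or 1 for male X)
.allele_copies <- function(cohort) {
  n <- n_samples(cohort)
  copies <- matrix(2L, n, n_variants(cohort))
  on_x <- cohort$variants$chrom == "X"
  if (any(on_x) && "sex" %in% names(cohort$samples)) {
    male <- !is.na(cohort$samples$sex) & cohort$samples$sex == "male"
    copies[male, on_x] <- 1L
  }
  copies
}

#' Re-orient dosages to count the minor allele
#'
#' Recomputes each variant's coded-allele frequency from the data (X males
#' contribute one allele) and flips the coding (dosage -> copies - dosage,
#' allele labels swapped) wherever the coded allele is in fact the major
#' one.  An exact 0.5 tie keeps the source coding, for determinism.
#'
#' @param cohort a `cohort`.
#' @return the cohort, minor-allele oriented, with variant `maf` updated.
#' @export
orient_to_minor <- function(cohort) {
  g <- cohort$genotypes
  copies <- .allele_copies(cohort)
  copies[is.na(g)] <- NA_integer_
  num <- colSums(g, na.rm = TRUE)
  den <- colSums(copies, na.rm = TRUE)
  f <- ifelse(den > 0, num / den, 0)
  flip <- which(f > 0.5)
  if (length(flip)) {
    g[, flip] <- copies[, flip] - g[, flip]
    ma <- cohort$variants$minor_allele[flip]
    cohort$variants$minor_allele[flip] <- cohort$variants$major_allele[flip]
    cohort$variants$major_allele[flip] <- ma
    f[flip] <- 1 - f[flip]
  }
  cohort$genotypes <- g
  cohort$variants$maf <- f
  cohort
}

#' Annotate variants with QC metrics
#'
#' Fills the `maf`, `missing_rate` and `hwe_p` columns of the variant table
#' (see [minor_allele_freq()], [snp_missingness()], [hwe_exact_p()]).  The
#' HWE test uses females only on chromosome X.
#'
#' @param cohort a `cohort`.
#' @return the cohort with annotated variant table.
#' @export
annotate_variants <- function(cohort) {
  cohort$variants$missing_rate <- snp_missingness(cohort)
  g <- cohort$genotypes
  copies <- .allele_copies(cohort)
  copies[is.na(g)] <- NA_integer_
  den <- colSums(copies, na.rm = TRUE)
  f <- ifelse(den > 0, colSums(g, na.rm = TRUE) / den, NA_real_)
  cohort$variants$maf <- pmin(f, 1 - f)
  cohort$variants$hwe_p <- hwe_scan(cohort)
  cohort
}

#' Subset a cohort
#'
#' @param cohort a `cohort`.
#' @param samples,variants index vectors (logical, integer or id character)
#'   into the sample/variant tables; `NULL` keeps all.
#' @return the subsetted `cohort`.
#' @export
subset_cohort <- function(cohort, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(cohort)) else samples
  vi <- if (is.null(variants)) seq_len(n_variants(cohort)) else variants
  if (is.character(si)) si <- match(si, cohort$samples$id)
  if (is.character(vi)) vi <- match(vi, cohort$variants$id)
  new_cohort(cohort$genotypes[si, vi, drop = FALSE],
             cohort$variants[vi, , drop = FALSE],
             cohort$samples[si, , drop = FALSE], validate = FALSE)
}

# ---------------------------------------------------------------------------
# readers / writers

.pheno_cols <- c("id", "sex", "age", "weight_kg", "height_m",
                 "sbp", "dbp", "on_med")

.read_pheno <- function(path) {
  ph <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                        colClasses = list(character = "id")))
  miss <- setdiff(.pheno_cols, names(ph))
  if (length(miss))
    stop("phenotype file lacks columns: ", paste(miss, collapse = ", "))
  ph$sex <- tolower(as.character(ph$sex))
  stopifnot(all(ph$sex %in% c("male", "female", NA)))
  ph$on_med <- as.logical(ph$on_med)
  ph
}

#' Read a genotype + phenotype cohort
#'
#' Reads genotypes from PLINK text (`.ped`/`.map`), PLINK 1 binary
#' (`.bed`/`.bim`/`.fam`) or an uncompressed biallelic-SNP VCF (via the
#' VariantAnnotation package), joins the tab-separated phenotype table
#' (columns `id, sex, age, weight_kg, height_m, sbp, dbp, on_med`), derives
#' BMI, medication-adjusted BP and hypertension status, and orients all
#' dosages to the minor allele as observed in the data.
#'
#' Genotyped samples absent from the phenotype file are retained and flagged
#' `phenotyped = FALSE` (they are excluded from association but not from the
#' genotype matrix); phenotype rows without genotypes are dropped with a
#' warning.
#'
#' @param genotype_path file prefix (PLINK formats) or `.vcf` path.
#' @param phenotype_path phenotype TSV, or `NULL` to skip phenotypes.
#' @param format one of `"plink_text"`, `"plink_binary"`, `"vcf"`.
#' @return a `cohort`.
#' @export
read_cohort <- function(genotype_path, phenotype_path = NULL,
                        format = c("plink_text", "plink_binary", "vcf")) {
  format <- match.arg(format)
  raw <- switch(format,
                plink_text = .read_ped_map(genotype_path),
                plink_binary = .read_bed(genotype_path),
                vcf = .read_vcf(genotype_path))
  samples <- data.frame(id = raw$sample_ids, stringsAsFactors = FALSE)
  if (!is.null(raw$sex)) samples$sex <- raw$sex
  if (!is.null(phenotype_path)) {
    ph <- .read_pheno(phenotype_path)
    if (anyDuplicated(ph$id))
      stop("duplicated sample ids in phenotype file")
    extra <- setdiff(ph$id, samples$id)
    if (length(extra))
      warning(length(extra), " phenotype rows without genotypes dropped")
    m <- match(samples$id, ph$id)
    samples$phenotyped <- !is.na(m)
    for (col in setdiff(.pheno_cols, "id")) samples[[col]] <- ph[[col]][m]
    if (!is.null(raw$sex)) {
      # phenotype file is authoritative for sex; fall back to .fam/.ped
      samples$sex <- ifelse(is.na(samples$sex), raw$sex, samples$sex)
    }
    samples <- prepare_samples(samples)
  } else {
    samples$phenotyped <- FALSE
  }
  co <- new_cohort(raw$genotypes, raw$variants, samples, validate = FALSE)
  co <- orient_to_minor(co)
  validate_cohort(co)
  annotate_variants(co)
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: writes the genotype files in the requested
#' format plus the phenotype TSV (`<prefix>.pheno.tsv`) when phenotypes are
#' present.
#'
#' @param cohort a `cohort`.
#' @param prefix output path prefix (extensions are appended).
#' @param format one of `"plink_text"`, `"plink_binary"`, `"vcf"`.
#' @return `prefix`, invisibly.
#' @export
write_cohort <- function(cohort, prefix,
                         format = c("plink_text", "plink_binary", "vcf")) {
  format <- match.arg(format)
  switch(format,
         plink_text = .write_ped_map(cohort, prefix),
         plink_binary = .write_bed(cohort, prefix),
         vcf = .write_vcf(cohort, paste0(prefix, ".vcf")))
  if ("sbp_raw" %in% names(cohort$samples) &&
      any(cohort$samples$phenotyped)) {
    s <- cohort$samples[cohort$samples$phenotyped, , drop = FALSE]
    ph <- data.frame(id = s$id, sex = s$sex, age = s$age,
                     weight_kg = s$weight_kg, height_m = s$height_m,
                     sbp = s$sbp_raw, dbp = s$dbp_raw,
                     on_med = as.integer(s$on_med))
    write.table(ph, paste0(prefix, ".pheno.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

# --- PLINK text ------------------------------------------------------------

.chrom_label <- function(x) {
  x <- as.character(x)
  x[x == "23"] <- "X"
  x
}

.read_ped_map <- function(prefix) {
  ped_f <- paste0(prefix, ".ped"); map_f <- paste0(prefix, ".map")
  if (!file.exists(ped_f) || !file.exists(map_f))
    stop("missing ", ped_f, " / ", map_f)
  map <- as.data.frame(data.table::fread(map_f, header = FALSE,
                                         colClasses = "character"))
  names(map) <- c("chrom", "id", "cm", "pos")[seq_len(ncol(map))]
  tok <- strsplit(trimws(readLines(ped_f)), "[ \t]+")   # PLINK: any ws
  tok <- tok[lengths(tok) > 0]
  m <- nrow(map)
  if (!all(lengths(tok) == 6 + 2 * m))
    stop(".ped rows must have 6 + 2*", m, " whitespace-separated fields")
  ped <- as.data.frame(do.call(rbind, tok), stringsAsFactors = FALSE)
  ids <- ped[[2]]
  sex <- c("male", "female")[match(ped[[5]], c("1", "2"))]
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  n <- nrow(ped)
  g <- matrix(NA_integer_, n, m)
  minor <- major <- character(m)
  chrom <- .chrom_label(map$chrom)
  male <- !is.na(sex) & sex == "male"
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    ok <- x1 != "0" & x2 != "0"
    al <- sort(unique(c(x1[ok], x2[ok])))
    if (length(al) > 2)
      stop("non-biallelic variant in .ped: ", map$id[j])
    if (length(al) == 0) al <- c("A", "B")
    if (length(al) == 1) al <- c(al, setdiff(c("A", "C", "G", "T"), al)[1])
    # count the first allele; orient_to_minor() fixes polarity later
    gj <- (x1 == al[1]) + (x2 == al[1])
    gj[!ok] <- NA_integer_
    if (chrom[j] == "X") {
      het_male <- male & !is.na(gj) & gj == 1L
      gj[het_male] <- NA_integer_        # invalid hemizygous call
      gj[male & !is.na(gj)] <- gj[male & !is.na(gj)] / 2L
    }
    g[, j] <- as.integer(gj)
    minor[j] <- al[1]; major[j] <- al[2]
  }
  variants <- data.frame(id = map$id, chrom = chrom,
                         pos = as.integer(map$pos),
                         minor_allele = minor, major_allele = major,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(ids)) stop("duplicated sample ids in .ped")
  if (anyDuplicated(variants$id)) stop("duplicated variant ids in .map")
  list(genotypes = g, variants = variants, sample_ids = ids, sex = sex)
}

.write_ped_map <- function(cohort, prefix) {
  v <- cohort$variants; s <- cohort$samples; g <- cohort$genotypes
  chrom_out <- ifelse(v$chrom == "X", "23", v$chrom)
  write.table(data.frame(chrom_out, v$id, 0, v$pos),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g); m <- ncol(g)
  male <- !is.na(s$sex) & s$sex == "male"
  alle <- matrix("0", n, 2 * m)
  for (j in seq_len(m)) {
    gj <- g[, j]
    if (v$chrom[j] == "X") gj[male] <- gj[male] * 2L   # homozygous convention
    x1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, v$minor_allele[j],
                                        v$major_allele[j]))
    x2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, v$minor_allele[j],
                                        v$major_allele[j]))
    alle[, 2 * j - 1] <- x1; alle[, 2 * j] <- x2
  }
  sexcode <- ifelse(is.na(s$sex), "0", ifelse(s$sex == "male", "1", "2"))
  phe <- if ("hypertensive" %in% names(s))
    ifelse(is.na(s$hypertensive), "-9",
           ifelse(s$hypertensive, "2", "1")) else "-9"
  ped <- cbind(s$id, s$id, "0", "0", sexcode, phe, alle)
  data.table::fwrite(as.data.frame(ped), paste0(prefix, ".ped"),
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(prefix)
}

# --- PLINK 1 binary (SNP-major .bed) ---------------------------------------

# 2-bit codes relative to .bim allele A1: 00 hom A1, 01 missing, 10 het,
# 11 hom A2; dosage counts A1.
.bed_decode_table <- function() {
  codes <- c(2L, NA_integer_, 1L, 0L)
  tab <- matrix(NA_integer_, 256, 4)
  for (b in 0:255)
    tab[b + 1, ] <- codes[bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L) + 1L]
  tab
}

.read_bed <- function(prefix) {
  bed_f <- paste0(prefix, ".bed")
  bim <- as.data.frame(data.table::fread(paste0(prefix, ".bim"),
                                         header = FALSE,
                                         colClasses = "character"))
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam <- as.data.frame(data.table::fread(paste0(prefix, ".fam"),
                                         header = FALSE,
                                         colClasses = "character"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(bed_f, "raw", n = file.size(bed_f))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file: ", bed_f)
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed supported")
  bpv <- ceiling(n / 4)
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  tab <- .bed_decode_table()
  g <- matrix(NA_integer_, n, m)
  idx <- seq_len(n)
  for (j in seq_len(m)) {
    dec <- tab[body[, j] + 1L, , drop = FALSE]   # bpv x 4, sample-ordered
    g[, j] <- as.integer(t(dec))[idx]
  }
  sex <- c("male", "female")[match(fam[[5]], c("1", "2"))]
  chrom <- .chrom_label(bim$chrom)
  male <- !is.na(sex) & sex == "male"
  on_x <- chrom == "X"
  if (any(on_x) && any(male)) {
    gx <- g[male, on_x, drop = FALSE]
    gx[!is.na(gx) & gx == 1L] <- NA_integer_     # het male -> missing
    gx[!is.na(gx) & gx == 2L] <- 1L
    g[male, on_x] <- gx
  }
  variants <- data.frame(id = bim$id, chrom = chrom,
                         pos = as.integer(bim$pos),
                         minor_allele = bim$a1, major_allele = bim$a2,
                         stringsAsFactors = FALSE)
  if (anyDuplicated(fam[[2]])) stop("duplicated sample ids in .fam")
  if (anyDuplicated(variants$id)) stop("duplicated variant ids in .bim")
  list(genotypes = g, variants = variants, sample_ids = fam[[2]], sex = sex)
}

.write_bed <- function(cohort, prefix) {
  v <- cohort$variants; s <- cohort$samples; g <- cohort$genotypes
  n <- nrow(g); m <- ncol(g)
  chrom_out <- ifelse(v$chrom == "X", "23", v$chrom)
  write.table(data.frame(chrom_out, v$id, 0, v$pos, v$minor_allele,
                         v$major_allele),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  sexcode <- ifelse(is.na(s$sex), "0", ifelse(s$sex == "male", "1", "2"))
  phe <- if ("hypertensive" %in% names(s))
    ifelse(is.na(s$hypertensive), "-9",
           ifelse(s$hypertensive, "2", "1")) else "-9"
  write.table(data.frame(s$id, s$id, 0, 0, sexcode, phe),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  male <- !is.na(s$sex) & s$sex == "male"
  on_x <- v$chrom == "X"
  code_of <- c(`0` = 3L, `1` = 2L, `2` = 0L)     # dosage -> 2-bit code
  bpv <- ceiling(n / 4)
  pad <- 4 * bpv - n
  out <- raw(3 + bpv * m)
  out[1:3] <- as.raw(c(0x6c, 0x1b, 0x01))
  for (j in seq_len(m)) {
    gj <- g[, j]
    if (on_x[j]) gj[male & !is.na(gj) & gj == 1L] <- 2L  # store hemi as hom
    cj <- code_of[as.character(gj)]
    cj[is.na(gj)] <- 1L
    cj <- c(cj, rep(0L, pad))
    q <- matrix(cj, nrow = 4)
    bytes <- colSums(q * c(1L, 4L, 16L, 64L))    # pack 4 codes per byte
    out[3 + (j - 1) * bpv + seq_len(bpv)] <- as.raw(bytes)
  }
  writeBin(out, paste0(prefix, ".bed"))
  invisible(prefix)
}

# --- VCF -------------------------------------------------------------------

.read_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF support requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt)
  if (any(nalt != 1))
    stop("non-biallelic variant(s): ",
         paste(head(names(rr)[nalt != 1], 5), collapse = ", "))
  gt <- VariantAnnotation::geno(vcf)$GT
  ids <- colnames(gt)
  dose <- matrix(NA_integer_, ncol(gt), nrow(gt))
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "0" = 0L, "1" = 1L)
  dose[] <- t(matrix(map[gt], nrow(gt), ncol(gt)))
  variants <- data.frame(
    id = names(rr),
    chrom = .chrom_label(sub("^chr", "", as.character(GenomicRanges::seqnames(rr)))),
    pos = GenomicRanges::start(rr),
    minor_allele = as.character(unlist(alt)),
    major_allele = as.character(VariantAnnotation::ref(vcf)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(ids)) stop("duplicated sample ids in VCF")
  if (anyDuplicated(variants$id)) stop("duplicated variant ids in VCF")
  list(genotypes = dose, variants = variants, sample_ids = ids, sex = NULL)
}

.write_vcf <- function(cohort, path) {
  v <- cohort$variants; g <- cohort$genotypes; s <- cohort$samples
  male <- !is.na(s$sex) & s$sex == "male"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", s$id), collapse = "\t")), con)
  gtmap <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g))) {
    gj <- g[, j]
    gt <- ifelse(is.na(gj), "./.", gtmap[gj + 1L])
    if (v$chrom[j] == "X")
      gt[male] <- ifelse(is.na(gj[male]), ".", as.character(gj[male]))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$major_allele[j],
                       v$minor_allele[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# gene intervals and pathways

#' Read gene intervals / pathway memberships
#'
#' Gene intervals come as a TSV with header columns `gene, chrom, start,
#' end` (1-based inclusive, extra columns ignored); pathways as a two-column
#' TSV `pathway, gene`, one row per membership.
#'
#' @param path input TSV.
#' @return `read_gene_intervals`: data.frame `gene, chrom, start, end`;
#'   `read_pathway_defs`: data.frame `pathway, gene`.
#' @export
read_gene_intervals <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(x)))
  x$chrom <- .chrom_label(x$chrom)
  stopifnot(all(x$start <= x$end))
  x[, c("gene", "chrom", "start", "end")]
}

#' @rdname read_gene_intervals
#' @export
read_pathway_defs <- function(path) {
  x <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  stopifnot(all(c("pathway", "gene") %in% names(x)))
  if (nrow(x) == 0) stop("empty pathway file")
  x[, c("pathway", "gene")]
}

#' Assign SNPs to gene intervals with flanking
#'
#' A SNP belongs to a gene iff its chromosome matches and its position lies
#' within `[start - flank_bp, end + flank_bp]`, bounds inclusive; the 20 kb
#' default captures proximal regulatory regions.  SNPs inside several
#' (overlapping) genes are assigned to each.
#'
#' @param variants variant table (`id`, `chrom`, `pos`).
#' @param genes data.frame `gene, chrom, start, end`.
#' @param flank_bp flank added to each side of every gene (bp).
#' @return named list: gene -> character vector of SNP ids (position order).
#' @export
assign_snps_to_genes <- function(variants, genes, flank_bp = 20000L) {
  stopifnot(flank_bp >= 0)
  ord <- order(variants$chrom, variants$pos)
  v <- variants[ord, , drop = FALSE]
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene
  for (i in seq_len(nrow(genes))) {
    hit <- v$chrom == genes$chrom[i] &
      v$pos >= genes$start[i] - flank_bp &
      v$pos <= genes$end[i] + flank_bp
    out[[i]] <- v$id[hit]
  }
  out
}

#' Resolve pathway definitions to SNP sets
#'
#' Takes the pathway->gene membership table and the gene->SNP map from
#' [assign_snps_to_genes()] and produces one definition per pathway with the
#' de-duplicated union of member-gene SNPs.  Pathway genes absent from the
#' gene map trigger a warning; empty pathways are retained.
#'
#' @param pathway_df data.frame `pathway, gene`.
#' @param gene_map named list gene -> SNP ids.
#' @return list of `pathway_def` lists: `name`, `genes`, `snp_ids`, `n_snps`.
#' @export
build_pathways <- function(pathway_df, gene_map) {
  if (nrow(pathway_df) == 0) stop("empty pathway definition table")
  missing <- setdiff(unique(pathway_df$gene), names(gene_map))
  if (length(missing))
    warning("pathway genes absent from gene list: ",
            paste(missing, collapse = ", "))
  lapply(split(pathway_df$gene, factor(pathway_df$pathway,
                                       levels = unique(pathway_df$pathway))),
         function(gs) {
           snps <- unique(unlist(gene_map[intersect(gs, names(gene_map))],
                                 use.names = FALSE))
           if (is.null(snps)) snps <- character(0)
           structure(list(name = NA_character_, genes = gs, snp_ids = snps,
                          n_snps = length(snps)), class = "pathway_def")
         }) -> defs
  for (i in seq_along(defs)) defs[[i]]$name <- names(defs)[i]
  defs
}
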