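sim_for_io <- function(seed = 5) {
  small_sim(seed, n = 40, n_pathways = 2, n_genes = 2, snps_per_gene = 5,
            missing_rate = 0.05)
}

test_that("plink text and binary round-trip dosages, ids and phenotypes", {
  sim <- sim_for_io()
  for (fmt in c("plink_text", "plink_binary")) {
    prefix <- file.path(withr::local_tempdir(), "co")
    write_cohort(sim$cohort, prefix, fmt)
    back <- read_cohort(prefix, paste0(prefix, ".pheno.tsv"), fmt)
    expect_identical(back$genotypes, sim$cohort$genotypes, label = fmt)
    expect_identical(back$samples$id, sim$cohort$samples$id)
    expect_identical(back$variants$id, sim$cohort$variants$id)
    expect_identical(back$variants$minor_allele,
                     sim$cohort$variants$minor_allele)
    expect_equal(back$samples$sbp_raw, sim$cohort$samples$sbp_raw)
    expect_equal(back$samples$on_med, sim$cohort$samples$on_med)
    expect_identical(back$samples$hypertensive,
                     sim$cohort$samples$hypertensive)
    expect_equal(back$samples$age, sim$cohort$samples$age,
                 tolerance = 1e-10)
  }
})

test_that("vcf round-trips through VariantAnnotation", {
  skip_if_not_installed("VariantAnnotation")
  sim <- sim_for_io(6)
  prefix <- file.path(withr::local_tempdir(), "co")
  write_cohort(sim$cohort, prefix, "vcf")
  back <- read_cohort(paste0(prefix, ".vcf"), paste0(prefix, ".pheno.tsv"),
                      "vcf")
  expect_identical(back$genotypes, sim$cohort$genotypes)
  expect_identical(back$variants$pos, sim$cohort$variants$pos)
})

test_that("a toy .ped decodes to hand-read dosages", {
  td <- withr::local_tempdir()
  # 3 samples x 5 SNPs; minor alleles by count: A, T, C, A, (monomorphic G)
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200", "1\trs3\t0\t300",
               "2\trs4\t0\t400", "2\trs5\t0\t500"),
             file.path(td, "toy.map"))
  writeLines(c(
    "F1\tP1\t0\t0\t1\t1\tA A\tT T\tC G\tA A\t0 0",
    "F2\tP2\t0\t0\t2\t2\tA G\tT G\tG G\tA G\tG G",
    "F3\tP3\t0\t0\t2\t1\tG G\tG G\tG G\tA G\tG G"),
    file.path(td, "toy.ped"))
  co <- read_cohort(file.path(td, "toy"), NULL, "plink_text")
  expect_equal(dim(co$genotypes), c(3L, 5L))
  # hand-decoded minor-allele dosages:
  # rs1 counts A (freq 3/6, tie keeps coding); rs2 counts G (tie, sorted
  # first); rs3 counts C (1/6); rs4's A has freq 4/6 so coding flips to G
  expect_equal(unname(co$genotypes[, 1]), c(2L, 1L, 0L))
  expect_equal(unname(co$genotypes[, 2]), c(0L, 1L, 2L))
  expect_equal(unname(co$genotypes[, 3]), c(1L, 0L, 0L))
  expect_equal(unname(co$genotypes[, 4]), c(0L, 1L, 1L))
  expect_equal(unname(co$genotypes[, 5]), c(NA_integer_, 0L, 0L))
  expect_false(any(co$samples$phenotyped))
})

test_that("dosages are re-oriented when the coded allele is major", {
  # coded-allele frequency 0.7 -> flipped to 0.3
  g <- matrix(c(2L, 2L, 1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L), ncol = 1)
  co <- make_test_cohort(g)
  co$variants$minor_allele <- "C"; co$variants$major_allele <- "T"
  out <- orient_to_minor(co)
  expect_equal(unname(out$variants$maf), 0.3)
  expect_equal(out$genotypes[, 1], 2L - g[, 1], ignore_attr = TRUE)
  expect_identical(out$variants$minor_allele, "T")
  # exact 0.5 tie keeps the source coding
  g2 <- matrix(c(0L, 1L, 1L, 2L), ncol = 1)
  out2 <- orient_to_minor(make_test_cohort(g2))
  expect_identical(out2$genotypes[, 1], g2[, 1], ignore_attr = TRUE)
})

test_that("samples without phenotype rows are flagged, not dropped", {
  sim <- sim_for_io(7)
  prefix <- file.path(withr::local_tempdir(), "co")
  write_cohort(sim$cohort, prefix, "plink_text")
  ph <- read.delim(paste0(prefix, ".pheno.tsv"))
  ph <- ph[-3, ]
  write.table(ph, paste0(prefix, ".pheno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  back <- read_cohort(prefix, paste0(prefix, ".pheno.tsv"), "plink_text")
  expect_equal(nrow(back$samples), nrow(sim$cohort$samples))
  dropped <- sim$cohort$samples$id[3]
  expect_false(back$samples$phenotyped[back$samples$id == dropped])
  expect_true(all(back$samples$phenotyped[back$samples$id != dropped]))
})

test_that("reader rejects malformed inputs with informative errors", {
  td <- withr::local_tempdir()
  writeLines("1\trs1\t0\t100", file.path(td, "bad.map"))
  writeLines(c("F1\tP1\t0\t0\t1\t1\tA C",
               "F2\tP2\t0\t0\t1\t1\tA G"), file.path(td, "bad.ped"))
  expect_error(read_cohort(file.path(td, "bad"), NULL, "plink_text"),
               "rs1")
  expect_error(read_cohort(file.path(td, "bad"), NULL, "nonsense"),
               "arg")
})

test_that("assign_snps_to_genes applies the inclusive 20 kb flank", {
  variants <- data.frame(
    id = c("a", "b", "c", "d"), chrom = c("1", "1", "1", "2"),
    pos = c(80000L, 79999L, 150000L, 120000L),
    minor_allele = "A", major_allele = "G")
  genes <- data.frame(gene = c("G1", "G2"), chrom = c("1", "1"),
                      start = c(100000L, 140000L),
                      end = c(130000L, 160000L))
  m <- assign_snps_to_genes(variants, genes, flank_bp = 20000L)
  expect_true("a" %in% m$G1)       # pos = start - 20000 exactly
  expect_false("b" %in% m$G1)      # one bp outside the flank
  expect_false("d" %in% m$G1)      # wrong chromosome
  expect_equal(sort(m$G2), "c")
  # SNP inside two overlapping genes appears in both
  genes2 <- data.frame(gene = c("Ga", "Gb"), chrom = "1",
                       start = c(60000L, 70000L), end = c(90000L, 95000L))
  m2 <- assign_snps_to_genes(variants, genes2, flank_bp = 0L)
  expect_true(all(c("a", "b") %in% m2$Ga))
  expect_true(all(c("a", "b") %in% m2$Gb))
})

test_that("build_pathways unions gene SNP sets and keeps variants distinct", {
  gene_map <- list(g1 = c("s1", "s2", "s3", "s4"),
                   g2 = c("s4", "s5", "s6"),
                   g3 = c("s7"))
  pw <- data.frame(pathway = c("P", "P", "P_minus", "Q"),
                   gene = c("g1", "g2", "g1", "ghost"))
  expect_warning(defs <- build_pathways(pw, gene_map), "ghost")
  expect_equal(defs$P$n_snps, 6)                 # shared s4 counted once
  expect_equal(defs$P_minus$snp_ids, gene_map$g1)
  expect_equal(defs$Q$n_snps, 0)                 # retained, empty
  expect_error(build_pathways(pw[0, ], gene_map), "empty")
})
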