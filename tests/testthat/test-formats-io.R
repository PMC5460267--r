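test_that("summary statistics round-trip through TSV, including gzip", {
  ss <- make_ss(3, beta = c(0.1, -0.2, 0), p = c(1e-6, 0.02, 1))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(ss, path)
  back <- read_summary_stats(path, trait_name = "trait")
  expect_equal(as.data.frame(back), as.data.frame(ss), tolerance = 1e-9)

  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_summary_stats(ss, gz)
  expect_equal(nrow(read_summary_stats(gz)), 3L)
})

test_that("dialect-driven column mapping handles foreign headers", {
  tab <- data.frame(MarkerName = c("rs1", "rs2"), CHR = "2",
                    BP = c(10L, 20L), A1 = c("A", "C"), A2 = c("G", "T"),
                    Effect = c(0.3, -0.1), StdErr = c(0.1, 0.1),
                    `P.value` = c(0.01, 0.5), check.names = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  dialect <- list(snp_id = "MarkerName", chrom = "CHR", pos = "BP",
                  effect_allele = "A1", other_allele = "A2",
                  beta = "Effect", se = "StdErr", p = "P.value")
  ss <- read_summary_stats(path, dialect = dialect)
  expect_equal(ss$snp_id, c("rs1", "rs2"))
  expect_equal(ss$beta, c(0.3, -0.1))

  # the same dialect can come from a YAML file
  ypath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(dialect, ypath)
  expect_equal(as.data.frame(read_summary_stats(path, dialect = ypath)),
               as.data.frame(ss))

  expect_error(read_summary_stats(path), class = "prscan_config_error")
})

test_that("invalid summary-statistic rows are rejected with a row report", {
  base <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
                     pos = c(100L, 200L), effect_allele = c("A", "C"),
                     other_allele = c("G", "T"), beta = 0.1, se = 0.1,
                     p = c(0.5, 0.5))
  bad_p <- base; bad_p$p[2] <- 0
  expect_error(summary_stats(bad_p), "row 2", class = "prscan_validation_error")
  same_alleles <- base; same_alleles$other_allele[1] <- "A"
  expect_error(summary_stats(same_alleles), "effect_allele",
               class = "prscan_validation_error")
  dup <- base; dup$snp_id[2] <- "rs1"
  expect_error(summary_stats(dup), "duplicate",
               class = "prscan_validation_error")
  bad_se <- base; bad_se$se <- c(0.1, -1)
  expect_error(summary_stats(bad_se), "se", class = "prscan_validation_error")

  # unparseable numerics in a file are row-level errors, not silent NAs
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos\teffect_allele\tother_allele\tbeta\tse\tp",
               "rs1\t1\t100\tA\tG\t0.1\t0.05\tnot_a_number"), path)
  expect_error(read_summary_stats(path), "unparseable",
               class = "prscan_validation_error")
})

test_that("BED coordinates convert to 1-based inclusive and round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tGENE1", path)
  annot <- read_gene_annotation(path)
  expect_equal(annot$genes$start, 1000L)
  expect_equal(annot$genes$end, 2000L)

  # empty file -> empty annotation
  empty <- withr::local_tempfile(fileext = ".bed")
  file.create(empty)
  expect_equal(nrow(read_gene_annotation(empty)$genes), 0L)

  # overlapping genes are both retained, unmerged
  writeLines(c("chr1\t0\t500\tA", "chr1\t100\t400\tB"), path)
  expect_equal(nrow(read_gene_annotation(path)$genes), 2L)

  # round-trip bijection on random intervals
  set.seed(11)
  start <- sample.int(1e6, 50)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:50), chrom = "chr2",
                      start = start, end = start + sample.int(1e4, 50))
  annot <- gene_annotation(genes)
  out <- withr::local_tempfile(fileext = ".bed")
  write_gene_annotation(annot, out)
  expect_equal(read_gene_annotation(out)$genes, annot$genes)

  # start > end after conversion is a validation error
  writeLines("chr1\t500\t100\tX", path)
  expect_error(read_gene_annotation(path), class = "prscan_validation_error")
})

test_that("gene annotation validates sub-feature nesting and kinds", {
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 100L, end = 500L)
  ok <- gene_annotation(genes, data.frame(gene_id = "G1", kind = "exon",
                                          start = 100L, end = 200L))
  expect_s3_class(ok, "gene_annotation")
  expect_error(
    gene_annotation(genes, data.frame(gene_id = "G1", kind = "exon",
                                      start = 50L, end = 200L)),
    "nest", class = "prscan_validation_error")
  expect_error(
    gene_annotation(genes, data.frame(gene_id = "G1", kind = "promoter",
                                      start = 100L, end = 200L)),
    class = "prscan_validation_error")
})

test_that("VCF genotypes convert to ALT dosages with missing kept missing", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gts <- rbind(c("0/1", "0/0"),
               c("./.", "1/1"),
               c("1|0", "0/1"))
  write_toy_vcf(vcf, gts, c("S1", "S2"))
  pheno <- write_pheno_tsv(withr::local_tempfile(fileext = ".tsv"),
                           c("S1", "S2"), c(1L, 0L))
  cohort <- read_target_cohort(vcf, pheno)
  expect_equal(dim(cohort$dosages), c(2L, 3L))
  expect_equal(unname(cohort$dosages["S1", ]), c(1, NA, 1))
  expect_equal(unname(cohort$dosages["S2", ]), c(0, 2, 1))
  expect_equal(cohort$phenotype, c(1L, 0L))

  # multi-allelic: first ALT with a warning
  write_toy_vcf(vcf, rbind(c("0/1", "1/1")), c("S1", "S2"),
                alt = "G,T")
  expect_warning(read_target_cohort(vcf, pheno), "multi-allelic")

  # sample mismatch lists the set difference
  bad_pheno <- write_pheno_tsv(withr::local_tempfile(fileext = ".tsv"),
                               c("S1", "S3"), c(1L, 0L))
  write_toy_vcf(vcf, gts, c("S1", "S2"))
  expect_error(read_target_cohort(vcf, bad_pheno), "S3",
               class = "prscan_config_error")
})

test_that("cohorts round-trip through dosage TSVs and synthetic VCF", {
  set.seed(21)
  dos <- matrix(sample(0:2, 24, replace = TRUE), nrow = 4)
  dos[1, 2] <- NA
  cohort <- make_cohort(dos, phenotype = c(1L, 1L, 0L, 0L))
  dir <- withr::local_tempdir()
  paths <- write_target_cohort(cohort, dir)
  back <- read_dosage_cohort(paths[["dosages"]], paths[["snp_index"]],
                             paths[["phenotype"]])
  expect_equal(unname(back$dosages), unname(cohort$dosages))
  expect_equal(back$phenotype, cohort$phenotype)

  vcf <- file.path(dir, "cohort.vcf")
  write_target_vcf(cohort, vcf)
  via_vcf <- read_target_cohort(vcf, paths[["phenotype"]])
  expect_equal(unname(via_vcf$dosages), unname(cohort$dosages))
  expect_equal(via_vcf$snp_index$snp_id, cohort$snp_index$snp_id)
})

test_that("write_results emits diffable TSV/JSON twins that round-trip", {
  tab <- data.frame(threshold = default_thresholds(),
                    assoc_p = c(1e-8, 0.2, 0.03, 0.5, 0.9, 0.04, 0.7),
                    r2 = runif(7))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_results(tab, tsv, "tsv")
  write_results(tab, json, "json")
  expect_equal(read_results(tsv), tab, tolerance = 1e-9)
  expect_equal(read_results(json), tab, tolerance = 1e-12)
  expect_equal(nrow(read_results(tsv)), 7L)

  # identical content twice -> byte-identical files (deterministic format)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_results(tab, tsv2, "tsv")
  expect_identical(readLines(tsv), readLines(tsv2))

  # empty gene list -> header-only TSV
  empty <- withr::local_tempfile(fileext = ".tsv")
  write_results(character(0), empty, "tsv")
  expect_equal(readLines(empty), "gene_id")
})
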