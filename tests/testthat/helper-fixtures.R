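# Fixture builders shared across test files. Everything is generated in
# code; no data files ship with the tests.

make_ss <- function(n = 5L, chrom = "1", pos = NULL, beta = NULL, p = NULL,
                    effect = "G", other = "A", trait = "trait",
                    ids = NULL) {
  summary_stats(data.frame(
    snp_id = ids %||% sprintf("rs%03d", seq_len(n)),
    chrom = chrom,
    pos = pos %||% (seq_len(n) * 1000L),
    effect_allele = effect,
    other_allele = other,
    beta = beta %||% rep(0.1, n),
    se = 0.05,
    p = p %||% rep(0.5, n)
  ), trait_name = trait)
}

random_ss <- function(n, max_pos = 1e6, trait = "trait") {
  make_ss(n,
          pos = sample.int(max_pos, n, replace = TRUE),
          beta = rnorm(n, sd = 0.1),
          p = runif(n),
          trait = trait)
}

random_annotation <- function(n_genes, max_pos = 1e6) {
  start <- sample.int(max_pos, n_genes, replace = TRUE)
  gene_annotation(data.frame(
    gene_id = sprintf("G%03d", seq_len(n_genes)),
    chrom = "1",
    start = start,
    end = start + sample.int(50000L, n_genes, replace = TRUE)
  ))
}

make_cohort <- function(dosages, pos = NULL, phenotype = NULL,
                        allele_a = "A", allele_b = "G", chrom = "1") {
  m <- ncol(dosages)
  target_cohort(
    sample_ids = sprintf("S%03d", seq_len(nrow(dosages))),
    snp_index = data.frame(
      snp_id = sprintf("rs%03d", seq_len(m)), chrom = chrom,
      pos = pos %||% (seq_len(m) * 1000L),
      allele_a = allele_a, allele_b = allele_b
    ),
    dosages = dosages,
    phenotype = phenotype
  )
}

write_toy_vcf <- function(path, gts, sample_ids, chrom = "1",
                          ids = NULL, ref = "A", alt = "G") {
  m <- nrow(gts)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  )
  body <- vapply(seq_len(m), function(i) {
    paste(c(chrom, i * 100L, (ids %||% sprintf("rs%03d", seq_len(m)))[i],
            ref, if (length(alt) > 1L) alt[i] else alt, ".", "PASS", ".",
            "GT", gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

write_pheno_tsv <- function(path, sample_ids, phenotype, ...) {
  extra <- list(...)
  tab <- data.frame(sample_id = sample_ids, phenotype = phenotype)
  for (nm in names(extra)) tab[[nm]] <- extra[[nm]]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
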