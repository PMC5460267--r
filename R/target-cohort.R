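#' Construct a target cohort
#'
#' Individual-level data for the cohort being scored: a samples x SNPs
#' dosage matrix (count of `allele_b`, in `[0, 2]`, `NA` for missing), a
#' binary phenotype and optional numeric covariates. Missing dosages are
#' kept as `NA` here; they are mean-imputed per SNP at scoring time only.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param snp_index data.frame with `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b` (one row per dosage column).
#' @param dosages numeric matrix, `length(sample_ids)` rows by
#'   `nrow(snp_index)` columns, values in `[0, 2]` or `NA`.
#' @param phenotype binary vector (case = 1, control = 0) or `NULL` while
#'   the cohort is still being simulated.
#' @param covariates optional data.frame of per-sample numeric covariates.
#' @return A `target_cohort` object.
#' @export
target_cohort <- function(sample_ids, snp_index, dosages, phenotype = NULL,
                          covariates = NULL) {
  sample_ids <- as.character(sample_ids)
  snp_index <- as.data.frame(snp_index)
  required <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  stopifnot(all(required %in% names(snp_index)))
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(sample_ids) ||
      ncol(dosages) != nrow(snp_index)) {
    prscan_abort(sprintf(
      "dosage matrix is %d x %d but there are %d samples and %d SNPs",
      nrow(dosages), ncol(dosages), length(sample_ids), nrow(snp_index)),
      "prscan_validation_error")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2)) {
    prscan_abort("dosage values must lie in [0, 2] or be missing",
                 "prscan_validation_error")
  }
  if (!is.null(phenotype)) {
    phenotype <- as.integer(phenotype)
    if (length(phenotype) != length(sample_ids) ||
        !all(phenotype %in% c(0L, 1L))) {
      prscan_abort("phenotype must be binary (0/1), one value per sample",
                   "prscan_validation_error")
    }
    if (sum(phenotype) == 0L || sum(phenotype) == length(phenotype)) {
      prscan_abort("phenotype needs at least one case and one control",
                   "prscan_validation_error")
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(sample_ids))
  }
  dimnames(dosages) <- list(sample_ids, snp_index$snp_id)
  structure(list(sample_ids = sample_ids, snp_index = snp_index,
                 dosages = dosages, phenotype = phenotype,
                 covariates = covariates),
            class = "target_cohort")
}

#' @export
print.target_cohort <- function(x, ...) {
  cat(sprintf("<target_cohort> %d samples x %d SNPs", nrow(x$dosages),
              ncol(x$dosages)))
  if (!is.null(x$phenotype)) {
    cat(sprintf("; %d cases / %d controls", sum(x$phenotype),
                sum(1L - x$phenotype)))
  }
  cat(sprintf("; %.2f%% missing dosages\n", 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Read a target cohort from VCF plus a phenotype table
#'
#' Genotypes are converted to dosages of the VCF ALT allele by counting `1`
#' alleles in the GT field; `.` alleles mark the genotype missing. Only the
#' first ALT allele of multi-allelic records is used (with a warning);
#' second-ALT alleles are treated as missing.
#'
#' @param vcf_path VCF file (plain or bgzipped) with GT genotypes.
#' @param phenotype_path TSV with columns `sample_id`, `phenotype`
#'   (case = 1 / control = 0) and optionally further numeric covariate
#'   columns.
#' @return A [target_cohort]. Fails with the set difference listed when the
#'   VCF and phenotype samples disagree.
#' @export
read_target_cohort <- function(vcf_path, phenotype_path) {
  if (!file.exists(vcf_path)) {
    prscan_abort(sprintf("VCF not found: %s", vcf_path),
                 "prscan_config_error")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix_mat <- vcfR::getFIX(vcf)
  if (is.null(dim(fix_mat))) fix_mat <- t(fix_mat)   # single-record VCF
  fix <- as.data.frame(fix_mat, stringsAsFactors = FALSE)
  alt_split <- strsplit(fix$ALT %||% character(0), ",", fixed = TRUE)
  multi <- lengths(alt_split) > 1L
  if (any(multi)) {
    warning(sprintf(
      "%d multi-allelic record(s): only the first ALT allele is used",
      sum(multi)), call. = FALSE)
  }
  snp_index <- data.frame(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    sprintf("%s:%s", fix$CHROM, fix$POS), fix$ID),
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    allele_a = fix$REF,
    allele_b = vapply(alt_split, `[`, character(1), 1L)
  )
  gt <- vcfR::extract.gt(vcf, element = "GT")
  doses <- gt_to_dosage(gt)               # SNPs x samples
  pheno <- read_phenotype_table(phenotype_path)
  vcf_samples <- colnames(doses)
  missing_in_pheno <- setdiff(vcf_samples, pheno$sample_id)
  missing_in_vcf <- setdiff(pheno$sample_id, vcf_samples)
  if (length(missing_in_pheno) || length(missing_in_vcf)) {
    prscan_abort(c(
      "sample sets of VCF and phenotype table differ:",
      if (length(missing_in_pheno))
        sprintf("  in VCF only: %s", paste(missing_in_pheno, collapse = ", ")),
      if (length(missing_in_vcf))
        sprintf("  in phenotype only: %s",
                paste(missing_in_vcf, collapse = ", "))),
      "prscan_config_error")
  }
  pheno <- pheno[match(vcf_samples, pheno$sample_id), , drop = FALSE]
  covar_cols <- setdiff(names(pheno), c("sample_id", "phenotype"))
  target_cohort(
    sample_ids = vcf_samples,
    snp_index = snp_index,
    dosages = t(doses),
    phenotype = pheno$phenotype,
    covariates = if (length(covar_cols)) pheno[covar_cols] else NULL
  )
}

#' Convert GT strings to ALT-allele dosages
#' @param gt character matrix of GT values (SNPs x samples).
#' @return numeric matrix of the same shape; `NA` where any allele is `.`.
#' @noRd
gt_to_dosage <- function(gt) {
  clean <- gsub("|", "/", gt, fixed = TRUE)
  u <- unique(as.vector(clean))
  dose_of <- vapply(u, function(g) {
    if (is.na(g)) return(NA_real_)
    alleles <- strsplit(g, "/", fixed = TRUE)[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles == "1")
  }, numeric(1))
  out <- matrix(dose_of[match(as.vector(clean), u)], nrow = nrow(gt),
                dimnames = dimnames(gt))
  out
}

#' Read a phenotype/covariate table keyed by sample id
#' @noRd
read_phenotype_table <- function(path) {
  if (!file.exists(path)) {
    prscan_abort(sprintf("phenotype table not found: %s", path),
                 "prscan_config_error")
  }
  tab <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                         colClasses = list(
                                           character = "sample_id"),
                                         showProgress = FALSE))
  if (!all(c("sample_id", "phenotype") %in% names(tab))) {
    prscan_abort("phenotype table needs columns 'sample_id' and 'phenotype'",
                 "prscan_config_error")
  }
  tab
}

#' Read a target cohort from a plain dosage matrix
#'
#' Alternative to VCF input: a TSV with one row per sample (`sample_id`
#' column first) and one column per SNP, plus a SNP index TSV with columns
#' `snp_id`, `chrom`, `pos`, `allele_a`, `allele_b`.
#'
#' @param dosage_path samples x SNPs dosage TSV.
#' @param snp_index_path SNP index TSV.
#' @param phenotype_path phenotype/covariate TSV as in
#'   [read_target_cohort()].
#' @return A [target_cohort].
#' @export
read_dosage_cohort <- function(dosage_path, snp_index_path, phenotype_path) {
  dos <- as.data.frame(data.table::fread(dosage_path, sep = "\t",
                                         header = TRUE,
                                         showProgress = FALSE))
  snp_index <- as.data.frame(data.table::fread(snp_index_path, sep = "\t",
                                               header = TRUE,
                                               showProgress = FALSE))
  sample_ids <- as.character(dos$sample_id)
  mat <- as.matrix(dos[setdiff(names(dos), "sample_id")])
  pheno <- read_phenotype_table(phenotype_path)
  if (!setequal(sample_ids, pheno$sample_id)) {
    prscan_abort("dosage and phenotype sample sets differ",
                 "prscan_config_error")
  }
  pheno <- pheno[match(sample_ids, pheno$sample_id), , drop = FALSE]
  covar_cols <- setdiff(names(pheno), c("sample_id", "phenotype"))
  target_cohort(sample_ids, snp_index, mat, pheno$phenotype,
                if (length(covar_cols)) pheno[covar_cols] else NULL)
}

#' Write a target cohort as dosage + SNP index + phenotype TSVs
#'
#' @param cohort a [target_cohort].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_target_cohort <- function(cohort, dir, prefix = "target") {
  stopifnot(inherits(cohort, "target_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    dosages = file.path(dir, paste0(prefix, "_dosages.tsv")),
    snp_index = file.path(dir, paste0(prefix, "_snps.tsv")),
    phenotype = file.path(dir, paste0(prefix, "_phenotype.tsv"))
  )
  dos <- data.frame(sample_id = cohort$sample_ids,
                    cohort$dosages, check.names = FALSE)
  data.table::fwrite(dos, paths[["dosages"]], sep = "\t", quote = FALSE)
  data.table::fwrite(cohort$snp_index, paths[["snp_index"]], sep = "\t",
                     quote = FALSE)
  pheno <- data.frame(sample_id = cohort$sample_ids,
                      phenotype = cohort$phenotype %||%
                        rep(NA_integer_, length(cohort$sample_ids)))
  if (!is.null(cohort$covariates)) pheno <- cbind(pheno, cohort$covariates)
  data.table::fwrite(pheno, paths[["phenotype"]], sep = "\t", quote = FALSE)
  invisible(paths)
}

#' Write integer-valued cohort genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with GT genotypes (`0/0`, `0/1`, `1/1`, `./.`);
#' usable only when all non-missing dosages are integers, as produced by the
#' package's genotype simulator.
#'
#' @param cohort a [target_cohort] with integer dosages.
#' @param path output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_target_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "target_cohort"))
  d <- cohort$dosages
  if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE)) {
    prscan_abort("VCF output requires integer dosages (hard genotypes)",
                 "prscan_validation_error")
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[round(t(d)) + 1L], nrow = ncol(d))   # SNPs x samples
  gt[is.na(gt)] <- "./."
  idx <- cohort$snp_index
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cohort$sample_ids), collapse = "\t"))
  body <- paste(idx$chrom, idx$pos, idx$snp_id, idx$allele_a, idx$allele_b,
                ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
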