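#' Construct a validated GWAS summary-statistics table
#'
#' A `summary_stats` object is a data.frame of per-SNP marginal association
#' records for one base trait: identifier, genomic position, the two
#' alleles, the per-allele effect size (`beta`, expressed for
#' `effect_allele`), its standard error and the association p-value.
#'
#' Invariants enforced: unique `snp_id`; `p` in (0, 1]; `se > 0`;
#' `pos >= 1`; `effect_allele != other_allele`. Violating rows are reported
#' individually and the constructor fails if any are present.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`.
#' @param trait_name name of the base trait the statistics describe.
#' @return A `summary_stats` object (data.frame subclass with a
#'   `trait_name` attribute).
#' @export
#' @examples
#' ss <- summary_stats(data.frame(
#'   snp_id = c("rs1", "rs2"), chrom = "1", pos = c(100L, 200L),
#'   effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'   beta = c(0.1, -0.2), se = c(0.02, 0.03), p = c(1e-6, 0.4)
#' ), trait_name = "HDL")
summary_stats <- function(records, trait_name = "trait") {
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "p")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    prscan_abort(
      sprintf("summary statistics lack mandatory column(s): %s",
              paste(missing_cols, collapse = ", ")),
      "prscan_config_error"
    )
  }
  records <- as.data.frame(records)[required]
  records$snp_id <- as.character(records$snp_id)
  records$chrom <- as.character(records$chrom)
  records$pos <- as.integer(records$pos)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  records$beta <- as.numeric(records$beta)
  records$se <- as.numeric(records$se)
  records$p <- as.numeric(records$p)

  problems <- validate_sumstats_rows(records)
  if (length(problems)) {
    prscan_abort(
      c(sprintf("%d summary-statistic row(s) failed validation:",
                length(problems)), head(problems, 20L)),
      "prscan_validation_error"
    )
  }
  structure(records,
            trait_name = as.character(trait_name),
            class = c("summary_stats", "data.frame"))
}

#' Per-row invariant report for summary statistics
#' @return character vector, one message per offending row (empty if clean).
#' @noRd
validate_sumstats_rows <- function(records) {
  problems <- character(0)
  bad <- function(which, why) {
    if (!any(which, na.rm = TRUE)) return(invisible())
    rows <- which(which | is.na(which))
    problems <<- c(problems, sprintf("row %d (%s): %s", rows,
                                     records$snp_id[rows], why))
  }
  bad(is.na(records$p) | records$p <= 0 | records$p > 1,
      "p must be in (0, 1]")
  bad(is.na(records$se) | records$se <= 0, "se must be > 0")
  bad(is.na(records$pos) | records$pos < 1, "pos must be >= 1")
  bad(is.na(records$beta), "beta must be numeric")
  bad(records$effect_allele == records$other_allele,
      "effect_allele must differ from other_allele")
  dup <- duplicated(records$snp_id)
  if (any(dup)) {
    problems <- c(problems, sprintf("row %d (%s): duplicate snp_id",
                                    which(dup), records$snp_id[dup]))
  }
  problems
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> trait '%s': %d SNPs on %d chromosome(s)\n",
              attr(x, "trait_name"), nrow(x),
              length(unique(x$chrom))))
  print(head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

#' Trait name of a summary-statistics set
#' @param x a `summary_stats` object.
#' @export
trait_name <- function(x) attr(x, "trait_name")

#' Read GWAS summary statistics from a delimited file
#'
#' Source files from different GWAS consortia use heterogeneous headers, so
#' the column mapping is configuration-driven rather than hard-coded: the
#' `dialect` maps the internal field names to the file's column names.
#' Gzip-compressed files are accepted transparently.
#'
#' @param path TSV (or gzipped TSV) file with a header row.
#' @param dialect named list/character vector mapping internal names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`,
#'   `se`, `p`) to the file's column names, or a path to a YAML file with
#'   such a mapping. Internal names absent from the mapping are assumed to
#'   match the file header verbatim.
#' @param trait_name trait label; defaults to the file name stem.
#' @return A validated [summary_stats] object. Rows violating the type
#'   invariants are reported per row and reading fails if any exist.
#' @export
read_summary_stats <- function(path, dialect = NULL, trait_name = NULL) {
  if (!file.exists(path)) {
    prscan_abort(sprintf("summary-statistics file not found: %s", path),
                 "prscan_config_error")
  }
  if (is.character(dialect) && length(dialect) == 1L && file.exists(dialect)) {
    dialect <- yaml::read_yaml(dialect)
  }
  internal <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "beta", "se", "p")
  map <- setNames(internal, internal)
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), internal)
    if (length(unknown)) {
      prscan_abort(sprintf("dialect maps unknown field(s): %s",
                           paste(unknown, collapse = ", ")),
                   "prscan_config_error")
    }
    map[names(dialect)] <- dialect
  }
  # everything is read as character and parsed explicitly below, so that a
  # malformed numeric is a reported row-level error, never a silent NA
  dt <- if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), sep = "\t", header = TRUE,
                      colClasses = "character", showProgress = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = "character", showProgress = FALSE)
  }
  missing_cols <- setdiff(unname(map), names(dt))
  if (length(missing_cols)) {
    prscan_abort(
      sprintf("mapped column(s) absent from header of %s: %s", path,
              paste(missing_cols, collapse = ", ")),
      "prscan_config_error"
    )
  }
  records <- as.data.frame(dt)[, unname(map)]
  names(records) <- internal
  numeric_fields <- c("pos", "beta", "se", "p")
  for (f in numeric_fields) {
    raw <- records[[f]]
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- is.na(parsed) & !is.na(raw) & trimws(as.character(raw)) != "NA"
    if (any(bad)) {
      prscan_abort(
        c(sprintf("unparseable numeric value(s) in column '%s':", map[[f]]),
          sprintf("row %d: '%s'", head(which(bad), 20L),
                  head(raw[bad], 20L))),
        "prscan_validation_error"
      )
    }
    records[[f]] <- parsed
  }
  summary_stats(records,
                trait_name = trait_name %||%
                  sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path)))
}

#' Write summary statistics as a TSV usable by [read_summary_stats()]
#'
#' Columns are emitted in the internal order with fixed 10-significant-digit
#' float formatting so outputs are diffable across runs.
#'
#' @param x a [summary_stats] object.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  out <- as.data.frame(x)
  for (f in c("beta", "se", "p")) out[[f]] <- format_fixed(out[[f]])
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}
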