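#' Write pipeline results with deterministic formatting
#'
#' Every tabular result is written with a fixed column order and fixed
#' 10-significant-digit float formatting so outputs are diffable; the JSON
#' twin carries the same table row-wise.
#'
#' @param results a `prs_scan`, `enrichment` result table, candidate gene
#'   set, or plain data.frame.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- results_table(results)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    out <- tab
    for (j in seq_along(out)) out[[j]] <- format_fixed(out[[j]])
    ok <- try(data.table::fwrite(out, path, sep = "\t", quote = FALSE),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      prscan_abort(sprintf("cannot write to %s", path), "prscan_io_error")
    }
  } else {
    ok <- try(jsonlite::write_json(tab, path, dataframe = "rows",
                                   digits = NA, na = "null",
                                   auto_unbox = TRUE),
              silent = TRUE)
    if (inherits(ok, "try-error")) {
      prscan_abort(sprintf("cannot write to %s", path), "prscan_io_error")
    }
  }
  invisible(path)
}

#' Coerce a result object to its canonical output table
#' @noRd
results_table <- function(results) {
  if (inherits(results, "prs_scan")) {
    results$table
  } else if (inherits(results, "candidate_gene_set")) {
    results$provenance
  } else if (inherits(results, "fdr_result")) {
    data.frame(p_raw = results$p_raw, q = results$q)
  } else if (is.character(results)) {
    data.frame(gene_id = results)
  } else if (is.data.frame(results)) {
    as.data.frame(results)
  } else {
    prscan_abort("unsupported result type for write_results",
                 "prscan_config_error")
  }
}

#' Read back a result table written by [write_results()]
#'
#' @param path TSV or JSON path produced by [write_results()].
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                    showProgress = FALSE))
  }
}
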