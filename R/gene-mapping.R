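#' Filter summary statistics to suggestively associated SNPs
#'
#' Keeps exactly the records with `p` strictly below `p_cut` (the
#' conventional "suggestive" association filter uses `p_cut = 1e-4`),
#' preserving input order.
#'
#' @param stats a [summary_stats] object.
#' @param p_cut p-value threshold in (0, 1]; strict inequality.
#' @return A [summary_stats] object with the selected records.
#' @export
select_snps <- function(stats, p_cut = 1e-4) {
  stopifnot(inherits(stats, "summary_stats"))
  if (!is.numeric(p_cut) || length(p_cut) != 1L || p_cut <= 0 || p_cut > 1) {
    prscan_abort("p_cut must be a single value in (0, 1]",
                 "prscan_config_error")
  }
  keep <- stats$p < p_cut
  out <- as.data.frame(stats)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, trait_name = trait_name(stats),
            class = c("summary_stats", "data.frame"))
}

#' Nominate candidate genes around associated SNPs
#'
#' A gene is nominated when some SNP lies inside the gene body (exon,
#' intron or UTR — any position within `[start, end]`) or within `window`
#' base pairs up- or downstream of the gene, i.e. when
#' `pos` falls in `[start - window, end + window]` on the same chromosome.
#' The window boundary is inclusive: a SNP exactly `window` bp away
#' qualifies. The default 100 kb window reflects the span within which most
#' cis-eQTL for a gene are found. Strand is ignored; the window is
#' symmetric. One SNP may support many genes and one gene many SNPs.
#'
#' @param snps a [summary_stats] object, normally already filtered with
#'   [select_snps()].
#' @param annot a [gene_annotation].
#' @param window non-negative window size in base pairs.
#' @param study label recorded in the provenance (which GWAS contributed the
#'   supporting SNP); defaults to the trait name.
#' @return A `candidate_gene_set`: `genes` (character vector, deduplicated,
#'   sorted) and `provenance` (data.frame `gene_id`, `snp_id`, `p`,
#'   `relation` in `{in_gene, within_window}`, `study`).
#' @export
map_snps_to_genes <- function(snps, annot, window = 100000L, study = NULL) {
  stopifnot(inherits(snps, "summary_stats"), inherits(annot,
                                                      "gene_annotation"))
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 0) {
    prscan_abort("window must be a single non-negative integer",
                 "prscan_config_error")
  }
  window <- as.integer(window)
  study <- study %||% trait_name(snps)
  genes <- annot$genes
  empty_prov <- data.frame(gene_id = character(0), snp_id = character(0),
                           p = numeric(0), relation = character(0),
                           study = character(0))
  if (nrow(snps) == 0L || nrow(genes) == 0L) {
    return(candidate_gene_set(empty_prov))
  }
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L)
  )
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - window),
                              end = genes$end + window)
  )
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(snp_gr, gene_gr, ignore.strand = TRUE)
  )
  if (length(hits) == 0L) return(candidate_gene_set(empty_prov))
  si <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  in_gene <- snps$pos[si] >= genes$start[gi] & snps$pos[si] <= genes$end[gi]
  prov <- data.frame(
    gene_id = genes$gene_id[gi],
    snp_id = snps$snp_id[si],
    p = snps$p[si],
    relation = ifelse(in_gene, "in_gene", "within_window"),
    study = study
  )
  candidate_gene_set(prov)
}

#' Construct a candidate gene set from a provenance table
#'
#' @param provenance data.frame with `gene_id`, `snp_id`, `p`, `relation`,
#'   `study`.
#' @return A `candidate_gene_set` object.
#' @export
candidate_gene_set <- function(provenance) {
  provenance <- as.data.frame(provenance)
  stopifnot(all(c("gene_id", "snp_id", "p", "relation", "study") %in%
                  names(provenance)))
  if (!all(provenance$relation %in% c("in_gene", "within_window"))) {
    prscan_abort("relation must be in_gene or within_window",
                 "prscan_validation_error")
  }
  provenance <- provenance[order(provenance$gene_id, provenance$p,
                                 provenance$snp_id), , drop = FALSE]
  rownames(provenance) <- NULL
  structure(list(genes = sort(unique(provenance$gene_id)),
                 provenance = provenance),
            class = "candidate_gene_set")
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat(sprintf(
    "<candidate_gene_set> %d genes, %d supporting SNP-gene pairs (%d in-gene)\n",
    length(x$genes), nrow(x$provenance),
    sum(x$provenance$relation == "in_gene")))
  invisible(x)
}

#' Merge candidate gene sets across studies
#'
#' Union of the gene sets with provenance concatenated per gene, so the set
#' records which study contributed each supporting SNP. Idempotent on
#' identical inputs.
#'
#' @param sets list of `candidate_gene_set` objects.
#' @return A single `candidate_gene_set`.
#' @export
merge_candidate_sets <- function(sets) {
  stopifnot(is.list(sets), all(vapply(sets, inherits, logical(1),
                                      "candidate_gene_set")))
  if (length(sets) == 0L) {
    return(candidate_gene_set(data.frame(
      gene_id = character(0), snp_id = character(0), p = numeric(0),
      relation = character(0), study = character(0))))
  }
  prov <- unique(do.call(rbind, lapply(sets, `[[`, "provenance")))
  candidate_gene_set(prov)
}
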