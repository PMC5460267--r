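#' Construct a gene annotation
#'
#' Internal coordinates are 1-based and inclusive on both ends (the GWAS
#' summary-statistics convention); BED input is converted at the boundary by
#' [read_gene_annotation()]. Optional sub-features (exon/intron/UTR) are
#' used only to label SNP-gene relations, never for inclusion decisions.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param sub_features optional data.frame with `gene_id`, `kind`
#'   (one of `"exon"`, `"intron"`, `"utr"`), `start`, `end`, nested within
#'   the parent gene interval.
#' @return A `gene_annotation` object.
#' @export
gene_annotation <- function(genes, sub_features = NULL) {
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    prscan_abort(sprintf("gene annotation lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")),
                 "prscan_config_error")
  }
  genes <- as.data.frame(genes)[required]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start > genes$end)) {
    bad <- which(genes$start > genes$end)
    prscan_abort(sprintf("gene %s has start > end (%d > %d)",
                         genes$gene_id[bad], genes$start[bad],
                         genes$end[bad]),
                 "prscan_validation_error")
  }
  if (any(genes$start < 1L)) {
    prscan_abort("gene start coordinates must be >= 1 (1-based inclusive)",
                 "prscan_validation_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    prscan_abort(sprintf("duplicate gene_id: %s",
                         paste(unique(genes$gene_id[
                           duplicated(genes$gene_id)]), collapse = ", ")),
                 "prscan_validation_error")
  }
  if (!is.null(sub_features)) {
    sub_features <- as.data.frame(sub_features)
    stopifnot(all(c("gene_id", "kind", "start", "end") %in%
                    names(sub_features)))
    if (!all(sub_features$kind %in% c("exon", "intron", "utr"))) {
      prscan_abort("sub-feature kind must be exon, intron or utr",
                   "prscan_validation_error")
    }
    idx <- match(sub_features$gene_id, genes$gene_id)
    if (anyNA(idx)) {
      prscan_abort("sub-feature references unknown gene_id",
                   "prscan_validation_error")
    }
    nested <- sub_features$start >= genes$start[idx] &
      sub_features$end <= genes$end[idx] &
      sub_features$start <= sub_features$end
    if (!all(nested)) {
      prscan_abort("sub-features must nest within their gene interval",
                   "prscan_validation_error")
    }
  }
  structure(list(genes = genes, sub_features = sub_features),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d genes on %d chromosome(s)%s\n",
              nrow(x$genes), length(unique(x$genes$chrom)),
              if (is.null(x$sub_features)) "" else
                sprintf(", %d sub-features", nrow(x$sub_features))))
  invisible(x)
}

#' Read gene intervals from a BED file
#'
#' BED uses 0-based half-open coordinates; they are converted here, exactly
#' once, to the internal 1-based inclusive convention
#' (`start_internal = start_bed + 1`, `end_internal = end_bed`). The
#' conversion is a bijection on intervals and is round-trip tested against
#' [write_gene_annotation()].
#'
#' @param path BED file with at least 3 columns; the gene name is taken from
#'   column 4 when present, otherwise synthesised as `chrom:start-end`.
#' @return A [gene_annotation] object (empty file gives an empty
#'   annotation). Overlapping genes are retained unmerged.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) {
    prscan_abort(sprintf("BED file not found: %s", path),
                 "prscan_config_error")
  }
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0))
  if (file.size(path) == 0L) return(gene_annotation(empty))
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           showProgress = FALSE)
  if (nrow(bed) == 0L) return(gene_annotation(empty))
  if (ncol(bed) < 3L) {
    prscan_abort("BED input needs at least 3 columns", "prscan_config_error")
  }
  genes <- data.frame(
    gene_id = if (ncol(bed) >= 4L) as.character(bed[[4L]]) else
      sprintf("%s:%d-%d", bed[[1L]], bed[[2L]], bed[[3L]]),
    chrom = as.character(bed[[1L]]),
    start = as.integer(bed[[2L]]) + 1L,
    end = as.integer(bed[[3L]])
  )
  gene_annotation(genes)
}

#' Write a gene annotation back to BED (0-based half-open)
#'
#' @param annot a [gene_annotation] object.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annot, path) {
  stopifnot(inherits(annot, "gene_annotation"))
  bed <- data.frame(chrom = annot$genes$chrom,
                    start = annot$genes$start - 1L,
                    end = annot$genes$end,
                    name = annot$genes$gene_id)
  data.table::fwrite(bed, path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}
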