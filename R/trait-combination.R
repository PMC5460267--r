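#' Names of the four beta-sign groups
#' @return character vector of the four combined-trait names.
#' @export
beta_sign_groups <- function() {
  c("incHDL+incLDL", "decHDL+decLDL", "incHDL+decLDL", "decHDL+incLDL")
}

#' Split matched SNPs of two traits into the four beta-sign groups
#'
#' SNPs present in both summary-statistic sets (matched by `snp_id`, betas
#' harmonized to a common effect allele) are partitioned by the signs of the
#' two effect sizes: increasing both, decreasing both, or one of the two
#' discordant patterns. SNPs with an exactly zero beta in either trait carry
#' no sign and are excluded and counted, as are SNPs that cannot be matched
#' or harmonized.
#'
#' @param hdl,ldl [summary_stats] objects for the two traits (named after
#'   the lipoprotein use case; any two traits work).
#' @return list with `groups` (named list of data.frames, one per group,
#'   columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `beta_hdl`, `beta_ldl`, `se_hdl`, `se_ldl`, `p_hdl`, `p_ldl`) and
#'   `counts` (`matched`, `unmatched`, `allele_mismatch`, `zero_beta`).
#' @export
split_by_beta_sign <- function(hdl, ldl) {
  stopifnot(inherits(hdl, "summary_stats"), inherits(ldl, "summary_stats"))
  a <- as.data.frame(hdl)
  b <- as.data.frame(ldl)
  idx <- match(a$snp_id, b$snp_id)
  n_unmatched <- sum(is.na(idx)) + sum(!(b$snp_id %in% a$snp_id))
  keep <- !is.na(idx)
  a <- a[keep, , drop = FALSE]
  b <- b[idx[keep], , drop = FALSE]

  same <- a$effect_allele == b$effect_allele & a$other_allele == b$other_allele
  flip <- a$effect_allele == b$other_allele & a$other_allele == b$effect_allele
  n_allele_mismatch <- sum(!(same | flip))
  ok <- same | flip
  a <- a[ok, , drop = FALSE]
  b <- b[ok, , drop = FALSE]
  beta_ldl <- ifelse(flip[ok], -b$beta, b$beta)

  zero <- a$beta == 0 | beta_ldl == 0
  n_zero <- sum(zero)
  a <- a[!zero, , drop = FALSE]
  b <- b[!zero, , drop = FALSE]
  beta_ldl <- beta_ldl[!zero]
  if (nrow(a) == 0L) {
    prscan_abort("no SNPs matched between the two traits",
                 "prscan_pipeline_error")
  }
  tab <- data.frame(
    snp_id = a$snp_id, chrom = a$chrom, pos = a$pos,
    effect_allele = a$effect_allele, other_allele = a$other_allele,
    beta_hdl = a$beta, beta_ldl = beta_ldl,
    se_hdl = a$se, se_ldl = b$se, p_hdl = a$p, p_ldl = b$p
  )
  group <- ifelse(tab$beta_hdl > 0,
                  ifelse(tab$beta_ldl > 0, "incHDL+incLDL", "incHDL+decLDL"),
                  ifelse(tab$beta_ldl > 0, "decHDL+incLDL", "decHDL+decLDL"))
  groups <- lapply(setNames(nm = beta_sign_groups()), function(g) {
    out <- tab[group == g, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  list(groups = groups,
       counts = c(matched = nrow(tab), unmatched = n_unmatched,
                  allele_mismatch = n_allele_mismatch, zero_beta = n_zero))
}

#' Equivalent weighted p-value of two p-values
#'
#' The harmonic-mean combination used when feeding a combined two-trait base
#' set to the scoring tool: `2 / p_eq = 1 / p_a + 1 / p_b`, i.e.
#' `p_eq = 2 * p_a * p_b / (p_a + p_b)`. Symmetric in its arguments, bounded
#' by `[min(p_a, p_b), max(p_a, p_b)]`, equal to either argument when they
#' coincide, and strictly increasing in each argument. Vectorized.
#'
#' @param p_hdl,p_ldl p-values in (0, 1].
#' @return p_eq in (0, 1].
#' @export
#' @examples
#' equivalent_p(0.01, 0.03)  # 0.015
equivalent_p <- function(p_hdl, p_ldl) {
  if (any(!is.finite(p_hdl)) || any(!is.finite(p_ldl)) ||
      any(p_hdl <= 0) || any(p_hdl > 1) || any(p_ldl <= 0) ||
      any(p_ldl > 1)) {
    prscan_abort("p-values must lie in (0, 1]", "prscan_validation_error")
  }
  # reciprocal form stays positive when both inputs are near the smallest
  # representable double (the product form can underflow to 0)
  2 / (1 / p_hdl + 1 / p_ldl)
}

#' Build a combined base trait from one beta-sign group
#'
#' Each record gets the equivalent weighted p-value of its two per-trait
#' p-values and a combined effect size for scoring. The combined beta
#' defaults to the arithmetic mean of the two harmonized betas (the two are
#' sign-consistent within a group by construction); alternatives keep one
#' trait's beta. The result is a valid [summary_stats] usable unchanged by
#' [scan_thresholds()], with the per-trait inputs carried as a `provenance`
#' attribute.
#'
#' @param group_tab one element of `split_by_beta_sign()$groups`.
#' @param name group name (one of [beta_sign_groups()]).
#' @param beta_rule `"mean"` (default), `"hdl"` or `"ldl"`.
#' @return A `combined_base` object (subclass of [summary_stats]).
#' @export
build_combined_base <- function(group_tab, name,
                                beta_rule = c("mean", "hdl", "ldl")) {
  beta_rule <- match.arg(beta_rule)
  if (nrow(group_tab) == 0L) {
    prscan_abort(sprintf("group '%s' contains no SNPs", name),
                 "prscan_pipeline_error")
  }
  beta <- switch(beta_rule,
                 mean = (group_tab$beta_hdl + group_tab$beta_ldl) / 2,
                 hdl = group_tab$beta_hdl,
                 ldl = group_tab$beta_ldl)
  out <- summary_stats(data.frame(
    snp_id = group_tab$snp_id, chrom = group_tab$chrom, pos = group_tab$pos,
    effect_allele = group_tab$effect_allele,
    other_allele = group_tab$other_allele,
    beta = beta,
    # se of the mean beta under independence; not used downstream of scoring
    se = sqrt(group_tab$se_hdl^2 + group_tab$se_ldl^2) / 2,
    p = equivalent_p(group_tab$p_hdl, group_tab$p_ldl)
  ), trait_name = name)
  attr(out, "provenance") <- group_tab[c("snp_id", "p_hdl", "p_ldl",
                                         "beta_hdl", "beta_ldl")]
  class(out) <- c("combined_base", class(out))
  out
}

#' Build all four combined base traits from two summary-statistic sets
#'
#' Convenience wrapper around [split_by_beta_sign()] and
#' [build_combined_base()]. Groups left empty by the split are dropped with
#' a message.
#'
#' @inheritParams split_by_beta_sign
#' @inheritParams build_combined_base
#' @return named list of `combined_base` objects with a `counts` attribute.
#' @export
combine_traits <- function(hdl, ldl, beta_rule = "mean") {
  sp <- split_by_beta_sign(hdl, ldl)
  keep <- names(sp$groups)[vapply(sp$groups, nrow, integer(1)) > 0L]
  dropped <- setdiff(beta_sign_groups(), keep)
  if (length(dropped)) {
    message(sprintf("empty beta-sign group(s) dropped: %s",
                    paste(dropped, collapse = ", ")))
  }
  out <- lapply(setNames(nm = keep), function(g) {
    build_combined_base(sp$groups[[g]], g, beta_rule)
  })
  attr(out, "counts") <- sp$counts
  out
}
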