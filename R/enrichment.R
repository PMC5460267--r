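#' Right-tailed Fisher's exact p-value for a 2x2 overlap table
#'
#' Probability that the overlap between a gene set of size `candidates` and
#' a network of `network_size` nodes, both drawn from a universe of
#' `universe` genes, is at least as large as observed:
#' `P(X >= overlap)` with `X ~ Hypergeometric(universe, candidates,
#' network_size)`. The tail is exact (no normal approximation).
#'
#' @param overlap observed count of candidate genes in the network.
#' @param network_size number of network nodes in the universe.
#' @param candidates number of candidate genes in the universe.
#' @param universe universe (reference set) size.
#' @return p-value in (0, 1].
#' @export
#' @examples
#' fisher_right_tail(5, 5, 5, 10)  # 1 / choose(10, 5)
fisher_right_tail <- function(overlap, network_size, candidates, universe) {
  for (v in list(overlap, network_size, candidates, universe)) {
    if (!is_count(v)) {
      prscan_abort("all margins must be single non-negative integers",
                   "prscan_validation_error")
    }
  }
  if (overlap > min(network_size, candidates) ||
      max(network_size, candidates) > universe ||
      overlap < max(0, network_size + candidates - universe)) {
    prscan_abort(sprintf(
      "inconsistent margins: overlap=%d, network=%d, candidates=%d, universe=%d",
      overlap, network_size, candidates, universe),
      "prscan_validation_error")
  }
  stats::phyper(overlap - 1, m = candidates, n = universe - candidates,
                k = network_size, lower.tail = FALSE)
}

#' Score networks for over-representation of candidate genes
#'
#' Computes, per network, the right-tailed Fisher's exact p-value for the
#' overlap between the candidate gene set and the network's nodes within an
#' explicit gene universe, and the enrichment score `-log10(p)` (base 10,
#' matching the convention for such scores and decimal reporting of the
#' p-values; switchable to natural log). Identifiers outside the universe
#' are dropped from both sides and counted.
#'
#' The universe must be supplied by the caller: the score is meaningless
#' without a declared reference set, and no default is shipped.
#'
#' @param candidates a `candidate_gene_set` or character vector of gene ids.
#' @param networks list of [interaction_network] objects.
#' @param universe character vector of all scoreable gene ids.
#' @param log_base 10 (default) or `exp(1)` for a natural-log score.
#' @return data.frame with one row per network, sorted by descending
#'   `score`, ties broken by descending `overlap` then `network_id`;
#'   columns `network_id`, `overlap`, `network_size`,
#'   `candidates_in_universe`, `universe_size`, `unmapped_nodes`,
#'   `p_right`, `score`.
#' @export
score_networks <- function(candidates, networks, universe, log_base = 10) {
  if (inherits(candidates, "candidate_gene_set")) {
    candidates <- candidates$genes
  }
  candidates <- unique(as.character(candidates))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    prscan_abort("the gene universe must be non-empty",
                 "prscan_config_error")
  }
  stopifnot(is.list(networks),
            all(vapply(networks, inherits, logical(1),
                       "interaction_network")))
  cand_u <- intersect(candidates, universe)
  unmapped_cand <- length(candidates) - length(cand_u)
  if (unmapped_cand > 0L) {
    message(sprintf("%d candidate gene(s) not in the universe were dropped",
                    unmapped_cand))
  }
  rows <- lapply(networks, function(nw) {
    nodes_u <- intersect(nw$nodes, universe)
    overlap <- length(intersect(nodes_u, cand_u))
    p <- fisher_right_tail(overlap, length(nodes_u), length(cand_u),
                           length(universe))
    data.frame(network_id = nw$network_id,
               overlap = overlap,
               network_size = length(nodes_u),
               candidates_in_universe = length(cand_u),
               universe_size = length(universe),
               unmapped_nodes = length(nw$nodes) - length(nodes_u),
               p_right = p,
               score = -log(p, base = log_base))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, -out$overlap, out$network_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
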