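#' Construct an interaction network
#'
#' Only node membership matters for enrichment scoring; edges are carried so
#' networks can be written back and inspected, and are validated for
#' consistency (endpoints in the node set, no self-loops).
#'
#' @param network_id network label.
#' @param nodes character vector of gene/protein identifiers.
#' @param edges optional two-column matrix/data.frame of unordered node
#'   pairs.
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(network_id, nodes, edges = NULL) {
  nodes <- unique(as.character(nodes))
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    stopifnot(ncol(edges) == 2L)
    edges <- matrix(as.character(edges), ncol = 2L)
    if (any(edges[, 1L] == edges[, 2L])) {
      prscan_abort("self-loops are not allowed", "prscan_validation_error")
    }
    loose <- setdiff(as.vector(edges), nodes)
    if (length(loose)) {
      prscan_abort(sprintf("edge endpoint(s) not in node set: %s",
                           paste(head(loose, 10L), collapse = ", ")),
                   "prscan_validation_error")
    }
    # canonical unordered representation
    edges <- unique(t(apply(edges, 1L, sort)))
  }
  structure(list(network_id = as.character(network_id), nodes = nodes,
                 edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> '%s': %d nodes, %d edges\n",
              x$network_id, length(x$nodes),
              if (is.null(x$edges)) 0L else nrow(x$edges)))
  invisible(x)
}

#' Read gene-set networks from a GMT file
#'
#' GMT dialect: one set per line, tab-separated `name`, `description`, then
#' member identifiers. Edges are irrelevant to enrichment scoring, so sets
#' read this way carry none.
#'
#' @param path GMT file.
#' @return list of [interaction_network] objects.
#' @export
read_networks_gmt <- function(path) {
  if (!file.exists(path)) {
    prscan_abort(sprintf("GMT file not found: %s", path),
                 "prscan_config_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      prscan_abort("GMT line needs name, description and >= 1 member",
                   "prscan_validation_error")
    }
    interaction_network(parts[1L], parts[-(1:2)])
  })
}

#' Read one network from node and edge list TSVs
#'
#' @param node_path TSV with a `node` column.
#' @param edge_path optional TSV with `from`/`to` columns.
#' @param network_id label; defaults to the node file stem.
#' @return An [interaction_network].
#' @export
read_network_tables <- function(node_path, edge_path = NULL,
                                network_id = NULL) {
  nodes <- as.data.frame(data.table::fread(node_path, sep = "\t",
                                           header = TRUE,
                                           showProgress = FALSE))
  stopifnot("node" %in% names(nodes))
  edges <- NULL
  if (!is.null(edge_path)) {
    ed <- as.data.frame(data.table::fread(edge_path, sep = "\t",
                                          header = TRUE,
                                          showProgress = FALSE))
    stopifnot(all(c("from", "to") %in% names(ed)))
    edges <- ed[c("from", "to")]
  }
  interaction_network(network_id %||% sub("\\.tsv$", "", basename(node_path)),
                      nodes$node, edges)
}
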