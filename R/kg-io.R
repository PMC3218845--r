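#' Load a knowledge graph from node/edge TSV tables
#'
#' Reads the package's TSV dialect: UTF-8, tab-delimited, header row
#' required.  The node table has columns `id`, `name`, `category`,
#' `synonyms` (pipe-separated); the edge table has `id_a`, `id_b`,
#' `semantic_type`, `source_db`, `references` (semicolon-separated).
#' Validation (unknown endpoints, malformed categories, self-loops,
#' duplicate collapsing) is performed by [knowledge_graph()].
#'
#' @param node_table path to the node TSV
#' @param edge_table path to the edge TSV
#' @return a `knowledge_graph` (unsanitized; see [sanitize()])
#' @export
load_graph <- function(node_table, edge_table) {
  for (p in c(node_table, edge_table))
    if (!file.exists(p)) stop("file not found: ", p)
  nodes <- utils::read.delim(node_table, sep = "\t", quote = "",
                             colClasses = "character",
                             na.strings = character(0),
                             fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE)
  edges <- utils::read.delim(edge_table, sep = "\t", quote = "",
                             colClasses = "character",
                             na.strings = character(0),
                             fileEncoding = "UTF-8",
                             stringsAsFactors = FALSE)
  knowledge_graph(nodes, edges)
}

#' Write a knowledge graph to node/edge TSV tables
#'
#' Inverse of [load_graph()]; `load_graph(write_graph_tsv(g, ...))`
#' round-trips the graph exactly.
#'
#' @param g knowledge_graph
#' @param node_table,edge_table output paths
#' @return invisibly, the two paths
#' @export
write_graph_tsv <- function(g, node_table, edge_table) {
  utils::write.table(g$nodes, node_table, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(g$relations, edge_table, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(node_table, edge_table))
}

#' Convert a knowledge graph to an igraph object
#'
#' @param g knowledge_graph
#' @param collapse if TRUE (default) one edge per distinct concept pair
#'   with provenance attributes aggregated (semicolon-joined); if FALSE
#'   a multigraph with one edge per relation row.
#' @return an undirected igraph graph with vertex attributes `name`
#'   (the concept id), `label`, `category`, `synonyms`, and edge
#'   attributes `semantic_type`, `source_db`, `references`.
#' @export
kg_as_igraph <- function(g, collapse = TRUE) {
  r <- g$relations
  if (collapse && nrow(r)) {
    key <- paste(r$id_a, r$id_b, sep = "\r")
    agg <- function(col) vapply(split(r[[col]], key)[unique(key)], function(v)
      paste(unique(v[nzchar(v)]), collapse = ";"), character(1))
    keep <- !duplicated(key)
    r <- data.frame(id_a = r$id_a[keep], id_b = r$id_b[keep],
                    semantic_type = unname(agg("semantic_type")),
                    source_db = unname(agg("source_db")),
                    references = unname(agg("references")),
                    stringsAsFactors = FALSE)
  }
  ig <- igraph::graph_from_data_frame(
    d = r, directed = FALSE,
    vertices = data.frame(name = g$nodes$id, label = g$nodes$name,
                          category = g$nodes$category,
                          synonyms = g$nodes$synonyms,
                          stringsAsFactors = FALSE))
  ig
}

#' Export a knowledge graph to GraphML
#'
#' Concept category/synonyms and relation semantic types, source
#' databases and literature references travel as GraphML attributes.
#' @param g knowledge_graph
#' @param path output file path
#' @param collapse see [kg_as_igraph()]
#' @export
write_graphml <- function(g, path, collapse = TRUE) {
  igraph::write_graph(kg_as_igraph(g, collapse = collapse), path,
                      format = "graphml")
  invisible(path)
}
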