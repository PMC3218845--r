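#' @importFrom stats setNames
NULL

#' Closed set of concept categories
#'
#' The semantic categories a concept in a knowledge graph may carry.
#' Mirrors the entity types found in curated biomedical resources:
#' genes/proteins, diseases, chemical compounds, pathways, ontology
#' annotation terms, protein domains, gene/disease families and
#' microRNAs, plus a catch-all `"other"`.
#'
#' @export
kg_categories <- function() {
  c("gene", "disease", "compound", "pathway", "annotation",
    "domain", "family", "mirna", "other")
}

# split/join helpers for the TSV list dialects
split_pipe <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1L]]
}
split_semi <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1L]]
}
join_semi <- function(x) paste(x, collapse = ";")

merge_reference_strings <- function(refs) {
  u <- unique(unlist(lapply(refs, split_semi)))
  join_semi(u)
}

#' Construct a heterogeneous knowledge graph
#'
#' Builds a typed, undirected knowledge graph from a node table and a
#' relation table.  Self-loop relations are dropped with a warning and
#' duplicate relations (same unordered endpoint pair, semantic type and
#' source database) are collapsed, merging their literature references.
#' Parallel relations between the same concept pair (different semantic
#' types or databases) are retained as provenance but count as a single
#' edge for random-walk transitions: all relations are equally weighed,
#' so a pair supported by five databases must not receive five times the
#' walk probability of a pair supported by one.
#'
#' @param nodes data.frame with character columns `id`, `name`,
#'   `category` (one of [kg_categories()]) and `synonyms`
#'   (pipe-separated, may be empty).
#' @param relations data.frame with character columns `id_a`, `id_b`,
#'   `semantic_type`, `source_db` and `references` (semicolon-separated,
#'   may be empty).
#' @return An object of class `knowledge_graph`: a list with elements
#'   `nodes` and `relations`.
#' @export
knowledge_graph <- function(nodes, relations) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  relations <- as.data.frame(relations, stringsAsFactors = FALSE)

  need_n <- c("id", "name", "category", "synonyms")
  if (!all(need_n %in% names(nodes)))
    stop("node table must have columns: ", paste(need_n, collapse = ", "))
  need_e <- c("id_a", "id_b", "semantic_type", "source_db", "references")
  if (!all(need_e %in% names(relations)))
    stop("edge table must have columns: ", paste(need_e, collapse = ", "))

  nodes <- nodes[need_n]
  relations <- relations[need_e]
  for (cc in need_n) nodes[[cc]] <- as.character(nodes[[cc]])
  for (cc in need_e) relations[[cc]] <- as.character(relations[[cc]])
  nodes$synonyms[is.na(nodes$synonyms)] <- ""
  relations$references[is.na(relations$references)] <- ""

  if (any(!nzchar(nodes$id)))
    stop("concept ids must be non-empty")
  if (anyDuplicated(nodes$id))
    stop("duplicate concept id(s): ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  bad_cat <- setdiff(unique(nodes$category), kg_categories())
  if (length(bad_cat))
    stop("malformed category value(s): ", paste(bad_cat, collapse = ", "),
         " (allowed: ", paste(kg_categories(), collapse = ", "), ")")

  unknown <- !(relations$id_a %in% nodes$id) | !(relations$id_b %in% nodes$id)
  if (any(unknown)) {
    row1 <- which(unknown)[1L]
    stop(sprintf("edge row %d references unknown concept id ('%s' -- '%s')",
                 row1, relations$id_a[row1], relations$id_b[row1]))
  }

  loops <- relations$id_a == relations$id_b
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop relation(s)", sum(loops)))
    relations <- relations[!loops, , drop = FALSE]
  }

  # canonical unordered endpoint representation
  a <- pmin(relations$id_a, relations$id_b)
  b <- pmax(relations$id_a, relations$id_b)
  relations$id_a <- a
  relations$id_b <- b

  key <- paste(a, b, relations$semantic_type, relations$source_db, sep = "\r")
  if (anyDuplicated(key)) {
    merged <- vapply(split(relations$references, key)[unique(key)],
                     merge_reference_strings, character(1))
    keep <- !duplicated(key)
    relations <- relations[keep, , drop = FALSE]
    relations$references <- unname(merged[match(key[keep], unique(key))])
  }
  rownames(nodes) <- NULL
  rownames(relations) <- NULL

  structure(list(nodes = nodes, relations = relations),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph: %d concepts, %d relations, %d walk edges>\n",
              nrow(x$nodes), nrow(x$relations), nrow(kg_walk_edges(x))))
  tab <- table(x$nodes$category)
  if (length(tab))
    cat("  categories:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Concept ids of a graph (stable indexing order)
#'
#' The order of this vector is the graph's dense integer index: position
#' `i` of any accessibility vector computed on the graph refers to
#' `kg_ids(g)[i]`.
#' @param g knowledge_graph
#' @export
kg_ids <- function(g) g$nodes$id

#' Number of concepts
#' @param g knowledge_graph
#' @export
kg_n_concepts <- function(g) nrow(g$nodes)

#' Number of (provenance-level) relations
#' @param g knowledge_graph
#' @export
kg_n_relations <- function(g) nrow(g$relations)

#' Unique walk edges of a graph
#'
#' Collapses parallel relations to one undirected edge per unordered
#' concept pair; these edges define random-walk transitions and degrees.
#' @param g knowledge_graph
#' @return data.frame with columns `id_a`, `id_b` (id_a < id_b), one row
#'   per distinct adjacent pair.
#' @export
kg_walk_edges <- function(g) {
  r <- g$relations
  keep <- !duplicated(paste(r$id_a, r$id_b, sep = "\r"))
  e <- r[keep, c("id_a", "id_b"), drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Walk degree of every concept
#'
#' Number of distinct neighboring concepts (parallel relations between
#' the same pair count once).
#' @param g knowledge_graph
#' @return named integer vector in graph index order.
#' @export
kg_degree <- function(g) {
  ids <- kg_ids(g)
  e <- kg_walk_edges(g)
  d <- setNames(integer(length(ids)), ids)
  if (nrow(e)) {
    tab <- table(factor(c(e$id_a, e$id_b), levels = ids))
    d[] <- as.integer(tab)
  }
  d
}

#' Adjacency list of distinct neighbors
#' @param g knowledge_graph
#' @return named list mapping concept id to character vector of neighbor ids.
#' @export
kg_neighbors <- function(g) {
  ids <- kg_ids(g)
  e <- kg_walk_edges(g)
  nb <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(nb)) nb[[i]] <- character(0)
  if (nrow(e)) {
    sa <- split(e$id_b, factor(e$id_a, levels = ids))
    sb <- split(e$id_a, factor(e$id_b, levels = ids))
    for (id in ids) nb[[id]] <- sort(unique(c(sa[[id]], sb[[id]])))
  }
  nb
}

stopifnot_concept <- function(g, id, what = "concept") {
  if (length(id) != 1L || !id %in% g$nodes$id)
    stop(sprintf("unknown %s id: %s", what, paste(id, collapse = ",")))
  invisible(id)
}

#' Restrict a graph to a set of concepts
#'
#' Keeps the given concepts (in original index order) and every relation
#' with both endpoints among them.
#' @param g knowledge_graph
#' @param ids character vector of concept ids to keep
#' @export
kg_subset <- function(g, ids) {
  nodes <- g$nodes[g$nodes$id %in% ids, , drop = FALSE]
  keep <- g$relations$id_a %in% ids & g$relations$id_b %in% ids
  relations <- g$relations[keep, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(relations) <- NULL
  structure(list(nodes = nodes, relations = relations),
            class = "knowledge_graph")
}

#' Provenance of the relation(s) between two adjacent concepts
#'
#' @param g knowledge_graph
#' @param a,b concept ids
#' @return data.frame of the relation rows connecting `a` and `b`
#'   (possibly several semantic types / source databases).
#' @export
kg_edge_provenance <- function(g, a, b) {
  lo <- min(a, b); hi <- max(a, b)
  r <- g$relations
  out <- r[r$id_a == lo & r$id_b == hi, , drop = FALSE]
  rownames(out) <- NULL
  out
}
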