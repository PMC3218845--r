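#' Sanitize a knowledge graph for random-walk analysis
#'
#' Keeps the largest connected component and then iteratively prunes
#' dangling concepts (concepts connected to only one other concept)
#' until none remain, i.e. reduces to the 2-core of the largest
#' component.  Removing a degree-1 concept can expose new degree-1
#' concepts, so pruning runs to a fixed point.  The result is connected
#' with minimum walk degree 2, or empty when no 2-core exists (e.g. a
#' tree).  The input graph is not modified.
#'
#' @param g non-empty knowledge_graph
#' @return sanitized knowledge_graph (possibly with zero concepts)
#' @export
sanitize <- function(g) {
  if (!inherits(g, "knowledge_graph")) stop("not a knowledge_graph")
  if (kg_n_concepts(g) == 0L) stop("cannot sanitize an empty graph")
  ig <- kg_as_igraph(g, collapse = TRUE)
  comp <- igraph::components(ig)
  big <- which.max(comp$csize)   # deterministic: first largest
  in_big <- igraph::V(ig)$name[comp$membership == big]
  sub <- igraph::induced_subgraph(ig, in_big)
  core <- igraph::coreness(sub)
  keep <- igraph::V(sub)$name[core >= 2]
  kg_subset(g, keep)
}

#' Is a graph sanitized (connected, min degree >= 2)?
#' @param g knowledge_graph
#' @export
is_sanitized <- function(g) {
  n <- kg_n_concepts(g)
  if (n == 0L) return(FALSE)
  d <- kg_degree(g)
  if (any(d < 2L)) return(FALSE)
  ig <- kg_as_igraph(g, collapse = TRUE)
  igraph::components(ig)$no == 1L
}

#' Remove every relation between two concepts
#'
#' Deletes all relations connecting `a` and `b`, whatever their semantic
#' type or source database; used by the leave-one-out benchmark to
#' disconnect a disease from its susceptibility gene.  No
#' re-sanitization is performed: the benchmark compares rankings over a
#' fixed concept set, and pruning after removal would change the
#' candidate set between queries.
#'
#' @param g knowledge_graph
#' @param a,b concept ids
#' @return knowledge_graph without the a--b relations
#' @export
remove_relations <- function(g, a, b) {
  stopifnot_concept(g, a)
  stopifnot_concept(g, b)
  lo <- min(a, b); hi <- max(a, b)
  keep <- !(g$relations$id_a == lo & g$relations$id_b == hi)
  g$relations <- g$relations[keep, , drop = FALSE]
  rownames(g$relations) <- NULL
  g
}

normalize_label <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Diseases related to a query disease by synonym substring
#'
#' A disease concept counts as related when at least one of its labels
#' (display name or synonym) contains the query disease's name as a
#' substring — e.g. "Charcot-Marie-Tooth disease, type 4C" is a variant
#' of "Charcot-Marie-Tooth", and a disease with synonym "Nephritis with
#' nerve deafness" is related to "Deafness".  Matching is
#' case-insensitive after whitespace normalization.  The query itself is
#' excluded.
#'
#' @param g knowledge_graph
#' @param disease concept id of category `disease`
#' @return character vector of related disease concept ids (possibly empty)
#' @export
related_diseases <- function(g, disease) {
  stopifnot_concept(g, disease, "disease")
  row <- g$nodes[g$nodes$id == disease, ]
  if (row$category != "disease")
    stop(sprintf("concept %s has category '%s', not 'disease'", disease, row$category))
  query <- normalize_label(row$name)
  cand <- g$nodes[g$nodes$category == "disease" & g$nodes$id != disease, , drop = FALSE]
  if (!nrow(cand)) return(character(0))
  hit <- vapply(seq_len(nrow(cand)), function(i) {
    labels <- c(cand$name[i], split_pipe(cand$synonyms[i]))
    any(grepl(query, normalize_label(labels), fixed = TRUE))
  }, logical(1))
  cand$id[hit]
}
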