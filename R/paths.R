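#' Probability of a simple path under the restart walk
#'
#' The probability that a walker that has survived restarts follows
#' exactly the given node sequence: one factor (1 - c)/degree(u) per
#' traversed edge, taken at the node the step leaves from (source up to
#' the penultimate node).  A zero-length path (source equals target) has
#' probability 1 (empty product).
#'
#' @param g knowledge_graph
#' @param nodes ordered character vector of concept ids, consecutive
#'   pairs adjacent, all distinct
#' @param restart_prob restart probability c in (0,1)
#' @return walk probability in (0, 1]
#' @export
path_probability <- function(g, nodes, restart_prob = 0.25) {
  if (anyDuplicated(nodes)) stop("path nodes must be distinct (simple path)")
  for (id in nodes) stopifnot_concept(g, id)
  if (length(nodes) < 2L) return(1)
  nb <- kg_neighbors(g)
  deg <- kg_degree(g)
  p <- 1
  for (i in seq_len(length(nodes) - 1L)) {
    u <- nodes[i]; v <- nodes[i + 1L]
    if (!v %in% nb[[u]])
      stop(sprintf("consecutive path nodes %s and %s are not adjacent", u, v))
    p <- p * (1 - restart_prob) / deg[[u]]
  }
  unname(p)
}

new_hypothesis_path <- function(g, nodes, probability) {
  steps <- if (length(nodes) >= 2L) {
    lapply(seq_len(length(nodes) - 1L), function(i) {
      prov <- kg_edge_provenance(g, nodes[i], nodes[i + 1L])
      list(from = nodes[i], to = nodes[i + 1L],
           semantic_types = prov$semantic_type,
           source_dbs = prov$source_db,
           references = unique(unlist(lapply(prov$references, split_semi))))
    })
  } else list()
  list(nodes = nodes, probability = probability, edges = steps)
}

path_key <- function(nodes) paste(nodes, collapse = "\r")

sort_paths <- function(paths) {
  if (!length(paths)) return(paths)
  probs <- vapply(paths, function(p) p$probability, numeric(1))
  keys <- vapply(paths, function(p) path_key(p$nodes), character(1))
  paths[order(-probs, keys)]
}

#' Exhaustively enumerate simple source-to-target paths (test oracle)
#'
#' Depth-first enumeration of every simple path from `source` to
#' `target` with at most `max_length` edges, with exact walk
#' probabilities, sorted by descending probability (ties by node
#' sequence).  Guarded to small inputs: at most 15 concepts or 1e5
#' paths.
#'
#' @param g knowledge_graph
#' @param source,target concept ids
#' @param max_length maximum number of edges per path
#' @param restart_prob restart probability c
#' @return list of paths, each a list with `nodes`, `probability`, `edges`
#' @export
enumerate_paths_exact <- function(g, source, target, max_length = 6L,
                                  restart_prob = 0.25) {
  stopifnot_concept(g, source)
  stopifnot_concept(g, target)
  if (kg_n_concepts(g) > 15L)
    stop(sprintf("enumeration guard exceeded: %d concepts > 15", kg_n_concepts(g)))
  nb <- kg_neighbors(g)
  deg <- kg_degree(g)
  found <- list()
  n_found <- 0L
  recurse <- function(path, prob) {
    head <- path[length(path)]
    if (head == target) {
      n_found <<- n_found + 1L
      if (n_found > 1e5L) stop("enumeration guard exceeded: more than 1e5 simple paths")
      found[[n_found]] <<- new_hypothesis_path(g, path, prob)
      return(invisible())
    }
    if (length(path) - 1L >= max_length) return(invisible())
    step <- (1 - restart_prob) / deg[[head]]
    for (v in nb[[head]]) {
      if (!v %in% path) recurse(c(path, v), prob * step)
    }
  }
  recurse(source, 1)
  sort_paths(found)
}

#' Extract the k most probable simple paths by backward backtracking
#'
#' Grows partial simple paths backward from the target toward the
#' source, following the backtracking heuristic: at each step the most
#' promising partial path is expanded through the neighbors of its
#' current head (considered in order of their accessibility with respect
#' to the source), extensions that revisit a node or exceed `max_length`
#' edges are discarded, and the frontier is pruned to the `beam_width`
#' most probable partials.  A partial path is scored by the walk
#' probability of its suffix as if walked from its current head toward
#' the target; every backward extension multiplies this score by
#' (1 - c)/degree(new head) < 1, so partials are expanded best-first and
#' complete paths emerge in non-increasing probability order.  Expansion
#' stops once k paths have been found (no remaining partial can beat
#' them) or the frontier empties.  With an unbounded beam the result is
#' exactly the top k of the exhaustive enumeration.
#'
#' @param g sanitized knowledge_graph
#' @param prior prior accessibility (used only when
#'   `order_by = "score"`; may be NULL otherwise)
#' @param posterior posterior accessibility computed from `source`
#' @param source,target distinct concept ids
#' @param k number of paths requested (default 10)
#' @param beam_width frontier cap (default 1000); `Inf` disables pruning
#' @param max_length maximum number of edges per path (default 6)
#' @param restart_prob restart probability c
#' @param order_by neighbor consideration order: posterior accessibility
#'   (default) or hub-corrected rank score posterior/sqrt(prior)
#' @return object of class `hypothesis_set`: list with `source`,
#'   `target`, `restart_prob`, `k_requested`, `paths` (sorted by
#'   descending probability) and the `graph`
#' @export
backtrack_paths <- function(g, prior = NULL, posterior, source, target,
                            k = 10L, beam_width = 1000L, max_length = 6L,
                            restart_prob = 0.25,
                            order_by = c("posterior", "score")) {
  order_by <- match.arg(order_by)
  stopifnot_concept(g, source)
  stopifnot_concept(g, target)
  if (source == target) stop("source and target must differ")
  if (k < 1L) stop("k must be positive")
  acc <- as.numeric(posterior[kg_ids(g)])
  names(acc) <- kg_ids(g)
  if (order_by == "score") {
    if (is.null(prior)) stop("order_by = 'score' requires a prior vector")
    acc <- acc / sqrt(as.numeric(prior[kg_ids(g)]))
  }
  nb <- kg_neighbors(g)
  deg <- kg_degree(g)
  # frontier of backward partials: nodes run head..target; prob is the
  # suffix walk probability from the head
  frontier <- list(list(nodes = target, prob = 1))
  f_prob <- 1
  f_key <- target
  results <- list()
  repeat {
    if (!length(frontier)) break
    best <- order(-f_prob, f_key)[1L]
    part <- frontier[[best]]
    frontier <- frontier[-best]
    f_prob <- f_prob[-best]
    f_key <- f_key[-best]
    head <- part$nodes[1L]
    if (head == source) {
      # recompute the probability in canonical source-to-target factor
      # order so exact ties sort identically to the enumeration oracle
      canon <- prod((1 - restart_prob) / deg[part$nodes[-length(part$nodes)]])
      results[[length(results) + 1L]] <- new_hypothesis_path(g, part$nodes, canon)
      if (length(results) >= k) {
        kth <- results[[k]]$probability
        if (!length(frontier) || max(f_prob) < kth * (1 - 1e-12)) break
      }
      next
    }
    if (length(part$nodes) - 1L >= max_length) next
    cand <- setdiff(nb[[head]], part$nodes)
    if (length(cand)) {
      cand <- cand[order(-acc[cand], cand)]
      for (u in cand) {
        nodes <- c(u, part$nodes)
        prob <- part$prob * (1 - restart_prob) / deg[[u]]
        frontier[[length(frontier) + 1L]] <- list(nodes = nodes, prob = prob)
        f_prob <- c(f_prob, prob)
        f_key <- c(f_key, path_key(nodes))
      }
    }
    if (is.finite(beam_width) && length(frontier) > beam_width) {
      keep <- order(-f_prob, f_key)[seq_len(beam_width)]
      frontier <- frontier[keep]
      f_prob <- f_prob[keep]
      f_key <- f_key[keep]
    }
  }
  results <- sort_paths(results)
  if (length(results) > k) results <- results[seq_len(k)]
  if (!length(results))
    message(sprintf("note: no simple path from %s to %s within %d steps",
                    source, target, max_length))
  structure(list(source = source, target = target,
                 restart_prob = restart_prob, k_requested = as.integer(k),
                 paths = results, graph = g),
            class = "hypothesis_set")
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat(sprintf("<hypothesis_set: %s -> %s, %d/%d path(s)>\n",
              x$source, x$target, length(x$paths), x$k_requested))
  for (p in x$paths[seq_len(min(5L, length(x$paths)))])
    cat(sprintf("  %.6g  %s\n", p$probability, paste(p$nodes, collapse = " - ")))
  if (length(x$paths) > 5L) cat(sprintf("  ... %d more\n", length(x$paths) - 5L))
  invisible(x)
}

#' Hypothesis subnetwork: union of the extracted paths
#'
#' Merges the paths of a hypothesis set into one annotated subnetwork.
#' Each edge carries its semantic types, source databases and literature
#' references, the best probability of any path using it, and an
#' importance tier in 1..3 (1 = most important; tiers split the distinct
#' best-probability values into three groups, mirroring
#' solid/dashed/dotted rendering of hypothesis figures).
#'
#' @param hs non-empty `hypothesis_set`
#' @return list of class `hypothesis_subnetwork` with `nodes`
#'   (data.frame `id`, `name`, `category`) and `edges` (data.frame
#'   `id_a`, `id_b`, `semantic_types`, `source_dbs`, `references`,
#'   `best_probability`, `tier`)
#' @export
hypothesis_subnetwork <- function(hs) {
  if (!inherits(hs, "hypothesis_set")) stop("not a hypothesis_set")
  if (!length(hs$paths)) stop("hypothesis set contains no paths")
  g <- hs$graph
  node_ids <- unique(unlist(lapply(hs$paths, function(p) p$nodes)))
  edge_best <- list()
  for (p in hs$paths) {
    for (st in p$edges) {
      key <- paste(min(st$from, st$to), max(st$from, st$to), sep = "\r")
      if (is.null(edge_best[[key]]) || p$probability > edge_best[[key]])
        edge_best[[key]] <- p$probability
    }
  }
  keys <- names(edge_best)
  best <- unlist(edge_best)
  u_desc <- sort(unique(best), decreasing = TRUE)
  tier_of <- floor(3 * (match(best, u_desc) - 1) / length(u_desc)) + 1L
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- do.call(rbind, lapply(seq_along(keys), function(i) {
    a <- parts[[i]][1]; b <- parts[[i]][2]
    prov <- kg_edge_provenance(g, a, b)
    data.frame(id_a = a, id_b = b,
               semantic_types = paste(unique(prov$semantic_type), collapse = ";"),
               source_dbs = paste(unique(prov$source_db), collapse = ";"),
               references = merge_reference_strings(prov$references),
               best_probability = best[i],
               tier = as.integer(tier_of[i]),
               stringsAsFactors = FALSE)
  }))
  edges <- edges[order(-edges$best_probability, edges$id_a, edges$id_b), ]
  rownames(edges) <- NULL
  nodes <- g$nodes[match(node_ids, g$nodes$id), c("id", "name", "category")]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, source = hs$source,
                 target = hs$target),
            class = "hypothesis_subnetwork")
}

#' Export a hypothesis subnetwork to GraphML
#' @param sn `hypothesis_subnetwork`
#' @param path output path
#' @export
write_subnetwork_graphml <- function(sn, path) {
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = sn$edges$id_a, to = sn$edges$id_b,
                   semantic_types = sn$edges$semantic_types,
                   source_dbs = sn$edges$source_dbs,
                   references = sn$edges$references,
                   best_probability = sn$edges$best_probability,
                   tier = sn$edges$tier, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = sn$nodes$id, label = sn$nodes$name,
                          category = sn$nodes$category, stringsAsFactors = FALSE))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' Serialize a hypothesis set to JSON
#'
#' Paths with node ids and display names, per-step provenance and
#' probabilities, suitable for downstream rendering.
#' @param hs `hypothesis_set`
#' @param path output path
#' @export
write_hypotheses_json <- function(hs, path) {
  g <- hs$graph
  obj <- list(
    source = hs$source, target = hs$target,
    restart_prob = hs$restart_prob, k_requested = hs$k_requested,
    paths = lapply(hs$paths, function(p) list(
      nodes = p$nodes,
      names = g$nodes$name[match(p$nodes, g$nodes$id)],
      probability = p$probability,
      edges = lapply(p$edges, function(st) list(
        from = st$from, to = st$to,
        semantic_types = st$semantic_types,
        source_dbs = st$source_dbs,
        references = st$references)))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
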