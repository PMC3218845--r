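# Independent oracles and small graph builders used across the suite.

# build a knowledge_graph from a plain edge list (ids as strings),
# everything category "other" unless a named categories vector is given
kg_from_edges <- function(edges, categories = NULL, isolated = character(0)) {
  ids <- sort(unique(c(edges[, 1], edges[, 2], isolated)))
  cat <- rep("other", length(ids))
  names(cat) <- ids
  if (!is.null(categories)) cat[names(categories)] <- categories
  nodes <- data.frame(id = ids, name = paste("node", ids), category = unname(cat),
                      synonyms = "", stringsAsFactors = FALSE)
  rel <- data.frame(id_a = edges[, 1], id_b = edges[, 2],
                    semantic_type = "association", source_db = "testdb",
                    references = "", stringsAsFactors = FALSE)
  knowledge_graph(nodes, rel)
}

# ring of n nodes plus n_chords random chords: always connected, min degree 2
rand_ring_kg <- function(n, n_chords = 0L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  ring <- cbind(ids, c(ids[-1], ids[1]))
  edges <- ring
  tries <- 0L
  while (n_chords > 0L && tries < 50L * n_chords) {
    pair <- sample(ids, 2L)
    key <- paste(sort(pair), collapse = "-")
    existing <- apply(edges, 1, function(r) paste(sort(r), collapse = "-"))
    if (!key %in% existing) {
      edges <- rbind(edges, pair)
      n_chords <- n_chords - 1L
    }
    tries <- tries + 1L
  }
  kg_from_edges(edges)
}

# independent sanitize oracle, written without igraph: restrict to the
# largest connected component, then iteratively prune degree-1 nodes
two_core_oracle <- function(g) {
  e <- kg_walk_edges(g)
  ids <- kg_ids(g)
  # connected components by repeated frontier expansion
  comps <- list()
  remaining <- ids
  while (length(remaining)) {
    comp <- remaining[1]
    repeat {
      grow <- unique(c(e$id_b[e$id_a %in% comp], e$id_a[e$id_b %in% comp]))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      comp <- c(comp, grow)
    }
    comps[[length(comps) + 1L]] <- comp
    remaining <- setdiff(remaining, comp)
  }
  ids <- comps[[which.max(lengths(comps))]]
  e <- e[e$id_a %in% ids & e$id_b %in% ids, , drop = FALSE]
  repeat {
    deg <- table(factor(c(e$id_a, e$id_b), levels = ids))
    drop <- names(deg)[deg <= 1L]
    if (!length(drop)) break
    ids <- setdiff(ids, drop)
    e <- e[e$id_a %in% ids & e$id_b %in% ids, , drop = FALSE]
  }
  sort(ids)
}

# brute-force AUC: fraction of positive/negative pairs the positive wins
auc_bruteforce <- function(positive_ranks, candidate_count) {
  neg <- setdiff(seq_len(candidate_count), positive_ranks)
  wins <- outer(positive_ranks, neg, FUN = function(p, q) (p < q) + 0.5 * (p == q))
  mean(wins)
}

# iterative-substitution oracle for the restart walk on a tiny graph:
# repeatedly apply the fixed-point map with dense arithmetic
posterior_oracle_dense <- function(g, source, c = 0.25, iters = 5000L) {
  ids <- kg_ids(g)
  nb <- kg_neighbors(g)
  deg <- kg_degree(g)
  n <- length(ids)
  Tm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (u in ids) Tm[nb[[u]], u] <- 1 / deg[[u]]
  e <- as.numeric(ids == source)
  p <- e
  for (i in seq_len(iters)) p <- c * e + (1 - c) * Tm %*% p
  setNames(as.numeric(p), ids)
}

# count simple paths up to max_length by a second strategy (adjacency walk
# with explicit stack rather than recursion)
count_simple_paths_stack <- function(g, source, target, max_length) {
  nb <- kg_neighbors(g)
  stack <- list(source)
  n <- 0L
  while (length(stack)) {
    path <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    head <- path[length(path)]
    if (head == target) { n <- n + 1L; next }
    if (length(path) - 1L >= max_length) next
    for (v in nb[[head]]) if (!v %in% path) stack[[length(stack) + 1L]] <- c(path, v)
  }
  n
}
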