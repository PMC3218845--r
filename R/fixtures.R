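# run code under a fixed seed without consuming global random state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic knowledge-graph fixture
#'
#' Describes a category-stratified random graph that emulates the
#' structural hazards of real integrated biomedical networks: several
#' concept categories, equally weighted edges, a small-world topology
#' induced by a few very high-degree hub nodes (the analogue of
#' ubiquitous compounds like ATP and water or generic annotation terms
#' like protein binding), and planted disease-gene associations
#' reachable through short heterogeneous evidence chains.
#'
#' @param n_genes,n_diseases,n_pathways,n_annotations,n_compounds
#'   numbers of concepts per category
#' @param n_hubs number of hub nodes, each wired to a large random
#'   fraction of the graph
#' @param planted list of planted associations; each element a list with
#'   `disease`, `gene`, `path_length` (>= 2 edges of indirect evidence)
#'   and optional `direct` (also add the direct disease-gene relation;
#'   default FALSE)
#' @param background_edge_prob per-pair probability of a background edge
#'   within each plausible category pair
#' @param hub_attach_prob probability a hub connects to any given
#'   non-hub node
#' @param seed integer seed; the same spec generates a byte-identical
#'   graph
#' @return list of class `fixture_spec`
#' @export
fixture_spec <- function(n_genes = 80L, n_diseases = 20L, n_pathways = 30L,
                         n_annotations = 40L, n_compounds = 28L,
                         n_hubs = 2L, planted = list(),
                         background_edge_prob = 0.01,
                         hub_attach_prob = 0.6, seed = 1L) {
  counts <- c(n_genes, n_diseases, n_pathways, n_annotations, n_compounds, n_hubs)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("fixture spec cannot be all-empty")
  for (p in planted) {
    if (is.null(p$disease) || is.null(p$gene) || is.null(p$path_length))
      stop("each planted triple needs disease, gene and path_length")
    if (p$path_length < 2) stop("planted path_length must be >= 2")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_diseases = as.integer(n_diseases),
                 n_pathways = as.integer(n_pathways),
                 n_annotations = as.integer(n_annotations),
                 n_compounds = as.integer(n_compounds),
                 n_hubs = as.integer(n_hubs), planted = planted,
                 background_edge_prob = background_edge_prob,
                 hub_attach_prob = hub_attach_prob,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

relation_row <- function(a, b, type, db, refs = "") {
  data.frame(id_a = a, id_b = b, semantic_type = type, source_db = db,
             references = refs, stringsAsFactors = FALSE)
}

# background edges for one category pair: Bernoulli over all pairs
sample_pair_edges <- function(ids_a, ids_b, p, type, db) {
  if (!length(ids_a) || !length(ids_b) || p <= 0) return(NULL)
  if (identical(ids_a, ids_b)) {
    if (length(ids_a) < 2L) return(NULL)
    pr <- t(utils::combn(ids_a, 2L))
  } else {
    pr <- as.matrix(expand.grid(ids_a, ids_b, stringsAsFactors = FALSE))
  }
  pick <- stats::runif(nrow(pr)) < p
  if (!any(pick)) return(NULL)
  relation_row(pr[pick, 1L], pr[pick, 2L], type, db)
}

semantic_for_pair <- function(cat_a, cat_b) {
  key <- paste(sort(c(cat_a, cat_b)), collapse = "|")
  switch(key,
         "gene|gene" = "protein interaction",
         "annotation|gene" = "annotation",
         "gene|pathway" = "pathway membership",
         "compound|gene" = "compound gene association",
         "compound|disease" = "compound disease association",
         "disease|disease" = "disease family",
         "disease|gene" = "disease gene association",
         "association")
}

#' Generate a synthetic knowledge graph from a fixture spec
#'
#' Produces a category-typed graph with Erdős–Rényi background edges
#' within plausible category pairs (gene-gene protein interactions,
#' gene-annotation, gene-pathway, compound-gene, compound-disease,
#' disease-disease family), hub nodes wired to a large random fraction
#' of all other nodes, and, for each planted association, an indirect
#' evidence chain of `path_length` heterogeneous edges from the disease
#' to the gene through non-hub intermediates (plus the direct
#' disease-gene relation when `direct = TRUE`).  Deterministic under the
#' spec's seed; global random state is left untouched.
#'
#' @param spec a [fixture_spec()]
#' @return unsanitized `knowledge_graph` (apply [sanitize()] before
#'   walking)
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop("not a fixture_spec")
  with_local_seed(spec$seed, {
    mk <- function(prefix, n, category) {
      if (n == 0L) return(NULL)
      ids <- sprintf("%s%d", prefix, seq_len(n))
      data.frame(id = ids, name = sprintf("%s %s", category, ids),
                 category = category, synonyms = "", stringsAsFactors = FALSE)
    }
    nodes <- rbind(mk("G", spec$n_genes, "gene"),
                   mk("D", spec$n_diseases, "disease"),
                   mk("P", spec$n_pathways, "pathway"),
                   mk("A", spec$n_annotations, "annotation"),
                   mk("C", spec$n_compounds, "compound"))
    hub_cat <- rep(c("compound", "annotation"), length.out = spec$n_hubs)
    if (spec$n_hubs > 0L) {
      hubs <- data.frame(id = sprintf("H%d", seq_len(spec$n_hubs)),
                         name = sprintf("hub %s H%d", hub_cat, seq_len(spec$n_hubs)),
                         category = hub_cat, synonyms = "",
                         stringsAsFactors = FALSE)
      nodes <- rbind(nodes, hubs)
    }

    ids_of <- function(cat) nodes$id[nodes$category == cat & !startsWith(nodes$id, "H")]
    p <- spec$background_edge_prob
    edges <- list(
      sample_pair_edges(ids_of("gene"), ids_of("gene"), p,
                        "protein interaction", "syndb_ppi"),
      sample_pair_edges(ids_of("gene"), ids_of("annotation"), p,
                        "annotation", "syndb_onto"),
      sample_pair_edges(ids_of("gene"), ids_of("pathway"), p,
                        "pathway membership", "syndb_pathway"),
      sample_pair_edges(ids_of("compound"), ids_of("gene"), p,
                        "compound gene association", "syndb_chem"),
      sample_pair_edges(ids_of("compound"), ids_of("disease"), p,
                        "compound disease association", "syndb_chem"),
      sample_pair_edges(ids_of("disease"), ids_of("disease"), p,
                        "disease family", "syndb_nosology"))

    # hubs: ubiquitous connections shortening paths between unrelated concepts
    non_hub <- nodes$id[!startsWith(nodes$id, "H")]
    if (spec$n_hubs > 0L) {
      for (h in sprintf("H%d", seq_len(spec$n_hubs))) {
        att <- non_hub[stats::runif(length(non_hub)) < spec$hub_attach_prob]
        if (length(att))
          edges[[length(edges) + 1L]] <-
            relation_row(h, att, "hub association", "syndb_hub")
      }
    }

    # planted indirect evidence chains
    inter_pool <- nodes$id[nodes$category %in% c("compound", "pathway", "annotation") &
                             !startsWith(nodes$id, "H")]
    for (pl in spec$planted) {
      n_inter <- pl$path_length - 1L
      if (n_inter > length(inter_pool))
        stop("not enough non-hub intermediate concepts for planted chain")
      inter <- sample(inter_pool, n_inter)
      chain <- c(pl$disease, inter, pl$gene)
      for (i in seq_len(length(chain) - 1L)) {
        ca <- nodes$category[nodes$id == chain[i]]
        cb <- nodes$category[nodes$id == chain[i + 1L]]
        edges[[length(edges) + 1L]] <-
          relation_row(chain[i], chain[i + 1L], semantic_for_pair(ca, cb),
                       "syndb_planted")
      }
      if (isTRUE(pl$direct))
        edges[[length(edges) + 1L]] <-
          relation_row(pl$disease, pl$gene, "disease gene association",
                       "syndb_dga")
    }

    knowledge_graph(nodes, do.call(rbind, edges))
  })
}

#' Deterministic toy graph for the prioritization principle
#'
#' A small hand-wired heterogeneous graph — eight genes, two diseases
#' and two protein domains connected by gene-disease associations,
#' gene-gene interactions, gene-domain annotations and a generic
#' "protein binding" hub annotation — built so that ranking the genes
#' from disease A illustrates specificity: gene G1, tightly embedded in
#' disease A's neighborhood, ranks first, while gene G8, reachable from
#' A only through the far end of an interaction chain and the hub, ranks
#' last.  The graph is a connected 2-core, so it passes [sanitize()]
#' unchanged.
#'
#' @return `knowledge_graph`
#' @export
example_disease_graph <- function() {
  nodes <- data.frame(
    id = c(sprintf("G%d", 1:8), "DA", "DB", "M1", "M2", "HUB"),
    name = c(sprintf("gene %d", 1:8), "disease A", "disease B",
             "domain 1", "domain 2", "protein binding"),
    category = c(rep("gene", 8), "disease", "disease", "domain", "domain",
                 "annotation"),
    synonyms = "", stringsAsFactors = FALSE)
  e <- function(a, b, type, db) relation_row(a, b, type, db)
  edges <- rbind(
    e("DA", "G1", "disease gene association", "curated_dga"),
    e("DA", "G2", "disease gene association", "curated_dga"),
    e("DA", "G3", "disease gene association", "curated_dga"),
    e("G1", "G2", "protein interaction", "curated_ppi"),
    e("G1", "G3", "protein interaction", "curated_ppi"),
    e("G1", "M1", "domain annotation", "curated_domains"),
    e("G2", "M1", "domain annotation", "curated_domains"),
    e("G3", "G4", "protein interaction", "curated_ppi"),
    e("G4", "M2", "domain annotation", "curated_domains"),
    e("G5", "M2", "domain annotation", "curated_domains"),
    e("G5", "G6", "protein interaction", "curated_ppi"),
    e("G6", "G7", "protein interaction", "curated_ppi"),
    e("G7", "G8", "protein interaction", "curated_ppi"),
    e("DB", "G7", "disease gene association", "curated_dga"),
    e("DB", "G8", "disease gene association", "curated_dga"),
    e("HUB", "G1", "annotation", "curated_onto"),
    e("HUB", "G2", "annotation", "curated_onto"),
    e("HUB", "G3", "annotation", "curated_onto"),
    e("HUB", "G4", "annotation", "curated_onto"),
    e("HUB", "G5", "annotation", "curated_onto"),
    e("HUB", "G6", "annotation", "curated_onto"),
    e("HUB", "G7", "annotation", "curated_onto"),
    e("HUB", "G8", "annotation", "curated_onto"))
  knowledge_graph(nodes, edges)
}

#' Deterministic hub-hazard fixture
#'
#' A source disease adjacent to a massive hub and, through two specific
#' low-degree intermediates, to a single gene two hops away.  The hub
#' collects more raw posterior mass than the gene (it is one step from
#' the source and fed back by its many satellites), yet the
#' hub-corrected rank score posterior/sqrt(prior) puts the specific gene
#' ahead — the configuration in which shortest-path or raw-proximity
#' ranking fails and the correction is required.
#'
#' @param n_satellites number of filler nodes attached to the hub
#'   (wired in a ring so the graph is a 2-core)
#' @return `knowledge_graph`
#' @export
hub_hazard_fixture <- function(n_satellites = 30L) {
  stopifnot(n_satellites >= 3L)
  sat <- sprintf("F%d", seq_len(n_satellites))
  nodes <- data.frame(
    id = c("S", "HUB", "I1", "I2", "GT", sat),
    name = c("source disease", "ubiquitous compound", "intermediate 1",
             "intermediate 2", "specific gene", sprintf("satellite %d", seq_len(n_satellites))),
    category = c("disease", "compound", "pathway", "annotation", "gene",
                 rep("other", n_satellites)),
    synonyms = "", stringsAsFactors = FALSE)
  edges <- rbind(
    relation_row("S", "HUB", "compound disease association", "syndb_chem"),
    relation_row("S", "I1", "association", "syndb_misc"),
    relation_row("S", "I2", "association", "syndb_misc"),
    relation_row("I1", "GT", "pathway membership", "syndb_pathway"),
    relation_row("I2", "GT", "annotation", "syndb_onto"),
    relation_row("HUB", sat, "compound gene association", "syndb_chem"),
    relation_row(sat, c(sat[-1], sat[1]), "association", "syndb_misc"))
  knowledge_graph(nodes, edges)
}

#' Write a fixture to node/edge TSV files
#' @param spec a [fixture_spec()]
#' @param node_table,edge_table output paths
#' @return the generated `knowledge_graph`, invisibly
#' @export
write_fixture_tsv <- function(spec, node_table, edge_table) {
  g <- generate_fixture(spec)
  write_graph_tsv(g, node_table, edge_table)
  invisible(g)
}
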