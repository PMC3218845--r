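# small heterogeneous graph used by the leave-one-out tests: gene GA has a
# direct disease link plus an indirect compound route; gene GZ hangs off
# the hub only (besides its direct link)
loo_test_kg <- function() {
  nodes <- data.frame(
    id = c("D1", "D2", sprintf("G%s", LETTERS[1:8]), "GZ", "C1", "A1", "H"),
    name = c("disease one", "disease two", sprintf("gene %s", LETTERS[1:8]),
             "gene Z", "compound one", "term one", "ubiquitous term"),
    category = c("disease", "disease", rep("gene", 9), "compound",
                 "annotation", "annotation"),
    synonyms = "", stringsAsFactors = FALSE)
  ids <- nodes$id
  hub_edges <- data.frame(id_a = "H", id_b = setdiff(ids, "H"),
                          semantic_type = "annotation", source_db = "onto",
                          references = "", stringsAsFactors = FALSE)
  e <- function(a, b, t = "association") data.frame(
    id_a = a, id_b = b, semantic_type = t, source_db = "db", references = "",
    stringsAsFactors = FALSE)
  edges <- rbind(
    hub_edges,
    e("D1", "GA", "disease gene association"),
    e("D1", "C1", "compound disease association"),
    e("C1", "GA", "compound gene association"),
    e("D1", "GZ", "disease gene association"),
    e("D1", "GB", "disease gene association"),
    e("GB", "GC", "protein interaction"),
    e("GC", "A1"), e("GD", "A1"),
    e("GE", "GF", "protein interaction"),
    e("D2", "GG", "disease gene association"),
    e("D2", "GH", "disease gene association"))
  knowledge_graph(nodes, edges)
}

test_that("rank score is posterior/sqrt(prior) with deterministic tie-break", {
  g <- kg_from_edges(rbind(c("s", "t1"), c("s", "t2"), c("t1", "t2")))
  # hand-built vectors: scores 0.02/sqrt(0.0004) = 1 and 0.01/sqrt(0.0001) = 1
  prior <- accessibility(c(s = 0.9995, t1 = 0.0004, t2 = 0.0001), "prior")
  post <- accessibility(c(s = 0.97, t1 = 0.02, t2 = 0.01), "posterior",
                        source = "s", restart_prob = 0.25)
  r <- rank_targets(g, prior, post, targets = c("t1", "t2"))
  expect_equal(r$score, c(1, 1))
  expect_equal(r$id, c("t1", "t2"))     # tie broken lexicographically
  # the source never appears among targets; missing ids are named
  expect_false("s" %in% r$id)
  expect_error(rank_targets(g, prior, post, targets = c("t1", "zz")), "zz")
})

test_that("score ordering is invariant to common rescaling of the inputs", {
  g <- hub_hazard_fixture()
  prior <- compute_prior(g)
  post <- compute_posterior(g, "S")
  r1 <- rank_targets(g, prior, post, target_category = "other")
  # rescale both vectors by positive constants (bypassing normalization)
  pr2 <- prior; post2 <- post
  attributes(pr2) <- attributes(prior); attributes(post2) <- attributes(post)
  pr2[] <- prior * 4; post2[] <- post * 0.5
  r2 <- suppressWarnings(rank_targets(g, pr2, post2, target_category = "other"))
  expect_equal(r2$id, r1$id)
})

test_that("dividing by sqrt(prior) lets a specific 2-hop gene beat the hub", {
  g <- hub_hazard_fixture()
  prior <- compute_prior(g)
  post <- compute_posterior(g, "S")
  r <- rank_targets(g, prior, post, targets = c("HUB", "GT"))
  expect_equal(r$id[1], "GT")                      # corrected score wins
  expect_gt(post[["HUB"]], post[["GT"]])           # raw posterior prefers the hub
})

test_that("roc_auc matches the stated extremes and the brute-force pairwise oracle", {
  expect_equal(roc_auc(1:3, 10)$auc, 1.0)
  expect_equal(roc_auc(8:10, 10)$auc, 0.0)
  # brute-force check of concrete small cases
  expect_equal(roc_auc(c(2, 5), 6)$auc, auc_bruteforce(c(2, 5), 6))
  expect_equal(roc_auc(c(2, 4), 6)$auc, 0.625)     # wins 5 of 8 pairs
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:40, 1)
    p <- sample(seq_len(n - 1), sample(seq_len(min(n - 1, 8)), 1))
    r <- roc_auc(p, n)
    expect_equal(r$auc, auc_bruteforce(p, n), info = paste("case", i))
    # trapezoidal area under the ROC points equals the Mann-Whitney AUC
    trap <- sum(diff(r$points$fpr) * (utils::head(r$points$tpr, -1) +
                                        utils::tail(r$points$tpr, -1)) / 2)
    expect_equal(trap, r$auc, tolerance = 1e-12, info = paste("case", i))
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  }
  expect_error(roc_auc(integer(0), 5), "no positive")
  expect_error(roc_auc(1:5, 5), "fewer than")
})

test_that("leave-one-out removes direct and related-disease links and records the rank", {
  g <- loo_test_kg()
  res <- loo_benchmark(g, "D1", "GA")
  expect_s3_class(res, "loo_result")
  expect_equal(res$record$removed_relation_count, 1L)
  expect_equal(nrow(kg_edge_provenance(res$graph, "D1", "GA")), 0L)
  # indirect compound route keeps GA in the top quartile of the 9 genes
  expect_lte(res$record$rank, ceiling(res$record$candidate_count / 4))
  # agreement with a ranking rebuilt from the exact dense solver
  ex_post <- solve_posterior_exact(res$graph, "D1")
  ex_rank <- rank_targets(res$graph, compute_prior(res$graph), ex_post,
                          target_category = "gene")
  expect_equal(res$record$rank, ex_rank$rank[ex_rank$id == "GA"])

  # a gene attached only through the hub drops to the bottom half
  res_z <- loo_benchmark(g, "D1", "GZ")
  expect_gt(res_z$record$rank, res_z$record$candidate_count / 2)

  expect_error(loo_benchmark(g, "D1", "C1"), "not target category")
})

test_that("removed relations are never used: re-adding them improves the rank", {
  g <- loo_test_kg()
  res <- loo_benchmark(g, "D1", "GA")
  # ranking recomputed on the intact graph (relation restored)
  full <- rank_targets(g, compute_prior(g), compute_posterior(g, "D1"),
                       target_category = "gene")
  expect_lte(full$rank[full$id == "GA"], res$record$rank)
})

test_that("related-disease links to the gene are removed too", {
  g <- loo_test_kg()
  # make D2 a variant of D1 by synonym and link it to GA
  g$nodes$synonyms[g$nodes$id == "D2"] <- "disease one, juvenile subtype"
  g$relations <- rbind(g$relations, data.frame(
    id_a = "D2", id_b = "GA", semantic_type = "disease gene association",
    source_db = "db2", references = "", stringsAsFactors = FALSE))
  g <- knowledge_graph(g$nodes, g$relations)
  res <- loo_benchmark(g, "D1", "GA")
  expect_equal(res$related_diseases, "D2")
  expect_equal(res$record$removed_relation_count, 2L)   # direct + variant link
  expect_equal(nrow(kg_edge_provenance(res$graph, "D2", "GA")), 0L)
})

test_that("benchmark summaries aggregate percentiles and AUCs", {
  rec <- data.frame(disease = c("D1", "D1", "D2"), gene = c("g1", "g2", "g3"),
                    removed_relation_count = 1L,
                    rank = c(1, 10, 100), candidate_count = 200,
                    percentile = c(0.005, 0.05, 0.5), stringsAsFactors = FALSE)
  s <- summarize_benchmark(rec)
  expect_equal(s$top1_frac, 1 / 3)
  expect_equal(s$top10_frac, 2 / 3)
  expect_equal(s$median_percentile, 0.05)
  expect_equal(s$pooled_auc, mean((200 - c(1, 10, 100)) / 199))
  expect_equal(s$mean_auc, mean(c(mean((200 - c(1, 10)) / 199), (200 - 100) / 199)))
  # single record: summary reduces to that record
  s1 <- summarize_benchmark(rec[1, ])
  expect_equal(s1$median_percentile, 0.005)
  expect_equal(s1$n_records, 1L)
})
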