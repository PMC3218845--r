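#' Rank target concepts against a source concept
#'
#' Each target is scored by its posterior accessibility from the source
#' divided by the square root of its prior accessibility.  The square
#' root correction penalizes globally over-accessible hub concepts
#' (ubiquitous compounds, generic annotation terms) whose high posterior
#' reflects centrality rather than specific relatedness, while not
#' penalizing well-connected concepts as harshly as full prior division
#' would.  Ties are broken lexicographically by concept id.
#'
#' @param g knowledge_graph the vectors were computed on
#' @param prior prior `accessibility` vector
#' @param posterior posterior `accessibility` vector (carries the source)
#' @param targets explicit character vector of target concept ids
#'   (alternative to `target_category`)
#' @param target_category restrict targets to one concept category
#' @return data.frame with columns `rank`, `id`, `name`, `category`,
#'   `score`, `posterior`, `prior`, sorted by descending score; the
#'   source concept is never among the targets.
#' @export
rank_targets <- function(g, prior, posterior, targets = NULL,
                         target_category = NULL) {
  ids <- kg_ids(g)
  if (!all(ids %in% names(prior)) || !all(ids %in% names(posterior)))
    stop("prior/posterior vectors do not cover the graph's concepts")
  source <- attr(posterior, "source")
  if (is.null(targets)) {
    if (is.null(target_category))
      stop("provide either `targets` or `target_category`")
    targets <- ids[g$nodes$category == target_category]
  } else {
    missing <- setdiff(targets, ids)
    if (length(missing))
      stop("target id(s) absent from graph: ", paste(missing, collapse = ", "))
  }
  targets <- setdiff(unique(targets), source)
  if (!length(targets)) stop("no targets to rank")
  post <- as.numeric(posterior[targets])
  pri <- as.numeric(prior[targets])
  score <- post / sqrt(pri)
  ord <- order(-score, targets)
  out <- data.frame(
    rank = seq_along(targets),
    id = targets[ord],
    name = g$nodes$name[match(targets[ord], g$nodes$id)],
    category = g$nodes$category[match(targets[ord], g$nodes$id)],
    score = score[ord],
    posterior = post[ord],
    prior = pri[ord],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Leave-one-out benchmark of a known disease-gene association
#'
#' Evaluates whether the method can recover a proven disease gene from
#' indirect evidence alone.  All direct relations between the disease
#' and the gene are removed, together with the gene's relations to every
#' related disease (variants/subtypes identified by the synonym
#' substring rule of [related_diseases()]) so that no prior direct
#' information remains.  The prior is recomputed on the modified graph
#' (edge removal changes degrees) unless `reuse_prior = TRUE`, the
#' posterior is computed from the disease, all concepts of
#' `target_category` are ranked, and the held-out gene's rank recorded.
#'
#' @param g sanitized knowledge_graph
#' @param disease,gene concept ids of the held-out association
#' @param restart_prob restart probability of the posterior walk
#' @param target_category category ranked as candidates (default "gene")
#' @param reuse_prior reuse the unmodified graph's prior (faster, off by
#'   default)
#' @param prior_method method passed to [compute_prior()]
#' @param tol,max_iter solver controls for [compute_posterior()]
#' @return object of class `loo_result`: list with `record` (one-row
#'   data.frame: disease, gene, removed_relation_count, rank,
#'   candidate_count, percentile), `ranking` (full ranked table),
#'   `graph` (the modified graph used for ranking) and
#'   `related_diseases`.
#' @export
loo_benchmark <- function(g, disease, gene, restart_prob = 0.25,
                          target_category = "gene", reuse_prior = FALSE,
                          prior_method = "closed_form",
                          tol = 1e-10, max_iter = 10000L) {
  stopifnot_concept(g, disease, "disease")
  stopifnot_concept(g, gene, "gene")
  gene_cat <- g$nodes$category[g$nodes$id == gene]
  if (gene_cat != target_category)
    stop(sprintf("held-out concept %s has category '%s', not target category '%s'",
                 gene, gene_cat, target_category))
  rel <- related_diseases(g, disease)
  n_before <- kg_n_relations(g)
  g2 <- remove_relations(g, disease, gene)
  for (d in rel) g2 <- remove_relations(g2, d, gene)
  removed <- n_before - kg_n_relations(g2)
  if (removed == 0L)
    message(sprintf("note: no direct %s--%s relation present to remove", disease, gene))
  prior <- if (reuse_prior) compute_prior(g, method = prior_method)
           else compute_prior(g2, method = prior_method)
  post <- compute_posterior(g2, disease, restart_prob = restart_prob,
                            tol = tol, max_iter = max_iter)
  ranking <- rank_targets(g2, prior, post, target_category = target_category)
  rank <- ranking$rank[ranking$id == gene]
  n_cand <- nrow(ranking)
  record <- data.frame(disease = disease, gene = gene,
                       removed_relation_count = removed,
                       rank = rank, candidate_count = n_cand,
                       percentile = rank / n_cand,
                       stringsAsFactors = FALSE)
  structure(list(record = record, ranking = ranking, graph = g2,
                 related_diseases = rel),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  r <- x$record
  cat(sprintf("<loo_result: %s vs %s, rank %d / %d (top %.2f%%), %d relation(s) removed>\n",
              r$gene, r$disease, r$rank, r$candidate_count,
              100 * r$percentile, r$removed_relation_count))
  invisible(x)
}

#' ROC curve and AUC from positive ranks
#'
#' Given the 1-based ranks of the positive candidates within a ranking
#' of `candidate_count` concepts, computes the ROC curve by sweeping the
#' rank threshold and the AUC as the Mann-Whitney probability that a
#' uniformly random positive outranks a uniformly random negative
#' (mid-rank tie handling; equals the trapezoidal area under the ROC
#' points).  A perfect ranking that puts every positive at the top
#' scores 1, a random ranking 0.5 in expectation.
#'
#' @param positive_ranks integer vector of distinct ranks in
#'   1..candidate_count
#' @param candidate_count total number of ranked candidates
#' @return list of class `roc_result` with `points` (data.frame `fpr`,
#'   `tpr`) and `auc`
#' @export
roc_auc <- function(positive_ranks, candidate_count) {
  if (!length(positive_ranks)) stop("no positive ranks supplied")
  if (anyDuplicated(positive_ranks))
    stop("positive ranks must be distinct (one rank per candidate)")
  if (any(positive_ranks < 1 | positive_ranks > candidate_count))
    stop("positive ranks must lie in 1..candidate_count")
  P <- length(positive_ranks)
  N <- candidate_count - P
  if (N <= 0) stop("positives must be fewer than candidates")
  pos <- sort(as.integer(positive_ranks))
  # threshold sweep: after admitting the top-k ranks
  is_pos <- rep(FALSE, candidate_count)
  is_pos[pos] <- TRUE
  tpr <- cumsum(is_pos) / P
  fpr <- cumsum(!is_pos) / N
  points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  # Mann-Whitney with mid-rank ties (ranks are distinct here, but keep
  # the general formula: positives "win" against negatives ranked worse)
  wins <- sum(vapply(pos, function(r) sum(r < setdiff(seq_len(candidate_count), pos)),
                     numeric(1)))
  auc <- wins / (P * N)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f, %d points>\n", x$auc, nrow(x$points)))
  invisible(x)
}

loo_records <- function(records) {
  if (inherits(records, "loo_result")) records <- list(records)
  if (is.data.frame(records)) return(records)
  do.call(rbind, lapply(records, function(r)
    if (inherits(r, "loo_result")) r$record else as.data.frame(r)))
}

#' Summarize a set of leave-one-out benchmark records
#'
#' Each record stems from an independent genome-wide prioritization, so
#' records are pooled on the percentile scale: a record with rank r
#' among n candidates contributes the pair-win fraction
#' (n - r)/(n - 1), i.e. the AUC of that single-positive ranking.
#' `pooled_auc` averages these fractions over all records;
#' `mean_auc` first averages within each disease, then across diseases.
#' Also reports the fraction of records ranked in the top 1% and top
#' 10% of their candidate set and the median percentile.
#'
#' @param records list of `loo_result` objects (or a data.frame of their
#'   `record` rows)
#' @return list with `mean_auc`, `pooled_auc`, `top1_frac`,
#'   `top10_frac`, `median_percentile`, `n_records`, `records`
#' @export
summarize_benchmark <- function(records) {
  rec <- loo_records(records)
  if (!nrow(rec)) stop("no benchmark records to summarize")
  rec_auc <- (rec$candidate_count - rec$rank) / (rec$candidate_count - 1)
  per_disease <- tapply(rec_auc, rec$disease, mean)
  list(mean_auc = mean(per_disease),
       pooled_auc = mean(rec_auc),
       top1_frac = mean(rec$percentile <= 0.01),
       top10_frac = mean(rec$percentile <= 0.10),
       median_percentile = stats::median(rec$percentile),
       n_records = nrow(rec),
       records = rec)
}
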