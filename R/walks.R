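#' Accessibility vector constructor
#'
#' A probability distribution over the concepts of a graph, either the
#' global ("prior") limit distribution of the uniform random walk or the
#' source-specific ("posterior") limit distribution of the walk with
#' restart.
#'
#' @param values numeric vector, named by concept id, non-negative,
#'   summing to 1 (within 1e-9)
#' @param role "prior" or "posterior"
#' @param source concept id of the restart source (posterior only)
#' @param restart_prob restart probability in (0,1) (posterior only)
#' @return numeric vector of class `accessibility` with attributes
#'   `role`, `source`, `restart_prob`
#' @export
accessibility <- function(values, role = c("prior", "posterior"),
                          source = NULL, restart_prob = NULL) {
  role <- match.arg(role)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("accessibility values must be named by concept id")
  if (any(values < 0)) stop("accessibility entries must be non-negative")
  if (abs(sum(values) - 1) > 1e-9)
    stop(sprintf("accessibility entries must sum to 1 (got %.12f)", sum(values)))
  if (role == "posterior") {
    if (is.null(source)) stop("posterior accessibility requires a source")
    if (is.null(restart_prob) || restart_prob <= 0 || restart_prob >= 1)
      stop("restart_prob must lie in (0,1)")
  } else {
    source <- NULL
    restart_prob <- NULL
  }
  structure(as.numeric(setNames(values, names(values))),
            names = names(values),
            role = role, source = source, restart_prob = restart_prob,
            class = "accessibility")
}

#' @export
print.accessibility <- function(x, ...) {
  cat(sprintf("<accessibility: role=%s%s, %d concepts>\n", attr(x, "role"),
              if (!is.null(attr(x, "source")))
                sprintf(", source=%s, restart_prob=%g",
                        attr(x, "source"), attr(x, "restart_prob")) else "",
              length(x)))
  invisible(x)
}

#' Column-stochastic transition operator of the uniform walk
#'
#' Entry (v, u) is 1/degree(u) when u and v are adjacent, 0 otherwise: a
#' walker at u steps to a uniformly random neighbor.  Parallel relations
#' count once (all relations are equally weighed).
#'
#' The graph must be connected with no isolated concepts; analysis
#' graphs normally come from [sanitize()], but graphs with degree-1
#' concepts are accepted because the leave-one-out benchmark removes
#' relations without re-sanitizing.
#'
#' @param g connected knowledge_graph without isolated concepts
#' @return sparse `dgCMatrix` with concept ids as dimnames; every column
#'   sums to exactly 1
#' @export
check_walkable <- function(g) {
  if (kg_n_concepts(g) == 0L) stop("graph is empty")
  d <- kg_degree(g)
  if (any(d == 0L))
    stop("graph has isolated concept(s): ",
         paste(utils::head(names(d)[d == 0L], 5L), collapse = ", "),
         "; sanitize() the graph first")
  if (igraph::components(kg_as_igraph(g))$no != 1L)
    stop("graph is not connected; sanitize() the graph first")
  invisible(TRUE)
}

transition_matrix <- function(g) {
  check_walkable(g)
  ids <- kg_ids(g)
  n <- length(ids)
  e <- kg_walk_edges(g)
  ia <- match(e$id_a, ids)
  ib <- match(e$id_b, ids)
  deg <- kg_degree(g)
  i <- c(ib, ia)            # row: destination v
  j <- c(ia, ib)            # col: origin u
  x <- 1 / deg[ids][j]
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                       dimnames = list(ids, ids))
}

#' Prior accessibility: limit distribution of the infinite uniform walk
#'
#' The probability of visiting each concept during an infinite random
#' walk measures global centrality and flags unspecific hubs.  On a
#' connected undirected graph this stationary distribution is
#' degree(v)/(2m) with m the number of distinct edges; `closed_form`
#' (the default and the reference semantics) returns it directly.
#' `power_iteration` iterates the lazy walk (stay put with probability
#' 1/2) from the uniform distribution until the successive-iterate L1
#' change falls below `tol`; the lazy walk shares the stationary
#' distribution of the plain walk but also converges on bipartite
#' (periodic) graphs.
#'
#' @param g sanitized knowledge_graph
#' @param method "closed_form" or "power_iteration"
#' @param tol L1 convergence tolerance (power iteration)
#' @param max_iter iteration cap (power iteration)
#' @return prior `accessibility` vector
#' @export
compute_prior <- function(g, method = c("closed_form", "power_iteration"),
                          tol = 1e-10, max_iter = 10000L) {
  method <- match.arg(method)
  if (method == "closed_form") {
    check_walkable(g)
    deg <- kg_degree(g)
    m <- nrow(kg_walk_edges(g))
    return(accessibility(deg / (2 * m), role = "prior"))
  }
  T <- transition_matrix(g)
  n <- ncol(T)
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- as.numeric(0.5 * x + 0.5 * (T %*% x))
    delta <- sum(abs(x_new - x))
    x <- x_new
    if (delta < tol)
      return(accessibility(setNames(x / sum(x), colnames(T)), role = "prior"))
  }
  stop(sprintf("prior power iteration did not converge in %d iterations (final L1 residual %.3e)",
               max_iter, delta))
}

#' Posterior accessibility: random walk with restart at a source
#'
#' Limit distribution p of the walk that at every step restarts at the
#' source concept with probability `restart_prob` (default 0.25) and
#' otherwise steps to a uniform random neighbor; the fixed point of
#' p = c * e_source + (1 - c) * T p.  Solved by fixed-point iteration,
#' which contracts at rate (1 - c) in L1.
#'
#' @param g sanitized knowledge_graph
#' @param source concept id the walk restarts at
#' @param restart_prob restart probability c in (0,1)
#' @param tol L1 convergence tolerance
#' @param max_iter iteration cap
#' @return posterior `accessibility` vector
#' @export
compute_posterior <- function(g, source, restart_prob = 0.25,
                              tol = 1e-10, max_iter = 10000L) {
  T <- transition_matrix(g)
  ids <- colnames(T)
  if (!source %in% ids) stop("unknown source id: ", source)
  if (restart_prob <= 0 || restart_prob >= 1)
    stop("restart_prob must lie in (0,1)")
  e <- as.numeric(ids == source)
  p <- e
  for (it in seq_len(max_iter)) {
    p_new <- restart_prob * e + (1 - restart_prob) * as.numeric(T %*% p)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      p <- p / sum(p)
      return(accessibility(setNames(p, ids), role = "posterior",
                           source = source, restart_prob = restart_prob))
    }
  }
  stop(sprintf("posterior iteration did not converge in %d iterations (final L1 residual %.3e)",
               max_iter, delta))
}

#' Exact posterior by dense linear solve (test oracle)
#'
#' Solves (I - (1-c) T) p = c e_source directly.  Intended as an
#' independent small-scale reference for [compute_posterior()]; guarded
#' against graphs larger than 5000 concepts, where the dense solve is no
#' longer reasonable.
#'
#' @inheritParams compute_posterior
#' @export
solve_posterior_exact <- function(g, source, restart_prob = 0.25) {
  T <- transition_matrix(g)
  n <- ncol(T)
  if (n > 5000L)
    stop(sprintf("dense solve guard exceeded: %d concepts > 5000", n))
  ids <- colnames(T)
  if (!source %in% ids) stop("unknown source id: ", source)
  if (restart_prob <= 0 || restart_prob >= 1)
    stop("restart_prob must lie in (0,1)")
  e <- as.numeric(ids == source)
  A <- diag(n) - (1 - restart_prob) * as.matrix(T)
  p <- solve(A, restart_prob * e)
  p <- pmax(p, 0)
  p <- p / sum(p)
  accessibility(setNames(p, ids), role = "posterior",
                source = source, restart_prob = restart_prob)
}

#' Write an accessibility vector to TSV
#'
#' Two-column table (`concept_id`, `probability`) preceded by `#`
#' metadata header lines recording the role, source and restart
#' probability.
#' @param x accessibility vector
#' @param path output path
#' @export
write_accessibility <- function(x, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# role: %s", attr(x, "role")), con)
  writeLines(sprintf("# source: %s",
                     if (is.null(attr(x, "source"))) "NA" else attr(x, "source")), con)
  writeLines(sprintf("# restart_prob: %s",
                     if (is.null(attr(x, "restart_prob"))) "NA"
                     else format(attr(x, "restart_prob"), digits = 17)), con)
  writeLines("concept_id\tprobability", con)
  writeLines(sprintf("%s\t%s", names(x), format(as.numeric(x), digits = 17,
                                                scientific = FALSE, trim = TRUE)), con)
  invisible(path)
}

#' Read an accessibility vector written by [write_accessibility()]
#' @param path input path
#' @export
read_accessibility <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta <- grep("^# ", lines, value = TRUE)
  get_meta <- function(key) {
    hit <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# ", key, ": "), "", hit[1])
  }
  role <- get_meta("role")
  source <- get_meta("source")
  restart <- get_meta("restart_prob")
  body <- lines[!grepl("^# ", lines)]
  tab <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                           stringsAsFactors = FALSE)
  accessibility(setNames(tab$probability, tab$concept_id), role = role,
                source = if (identical(source, "NA")) NULL else source,
                restart_prob = if (identical(restart, "NA")) NULL
                               else as.numeric(restart))
}
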