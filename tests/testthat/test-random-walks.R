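triangle_kg <- function() kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("a", "c")))

test_that("transition operator is column-stochastic with 1/degree entries", {
  T <- transition_matrix(triangle_kg())
  expect_equal(unname(Matrix::colSums(T)), rep(1, 3))
  expect_equal(T["b", "a"], 0.5)
  expect_equal(T["a", "a"], 0)

  # star K1,3: leaves walk to the center with probability 1
  star <- kg_from_edges(rbind(c("c", "l1"), c("c", "l2"), c("c", "l3")))
  Ts <- transition_matrix(star)
  expect_equal(unname(Ts[c("l1", "l2", "l3"), "c"]), rep(1 / 3, 3))
  expect_equal(Ts["c", "l1"], 1)
  expect_equal(unname(Matrix::colSums(Ts)), rep(1, 4))

  # column sums exactly 1 on random 2-core graphs
  for (seed in 1:5) {
    g <- rand_ring_kg(15, 8, seed = seed)
    expect_equal(unname(Matrix::colSums(transition_matrix(g))), rep(1, 15))
  }

  # isolated concept or disconnected graph is rejected
  disc <- kg_from_edges(rbind(c("a", "b"), c("c", "d")))
  expect_error(transition_matrix(disc), "not connected")
})

test_that("prior equals degree/(2m): symmetric, regular and wheel cases", {
  expect_equal(unname(as.numeric(compute_prior(triangle_kg()))), rep(1 / 3, 3))

  c4 <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  expect_equal(unname(as.numeric(compute_prior(c4))), rep(1 / 4, 4))

  # wheel on 4 rim nodes: hub degree 4, rim degree 3, m = 8
  w4 <- kg_from_edges(rbind(c("h", "r1"), c("h", "r2"), c("h", "r3"), c("h", "r4"),
                            c("r1", "r2"), c("r2", "r3"), c("r3", "r4"), c("r4", "r1")))
  pr <- compute_prior(w4)
  expect_equal(pr[["h"]], 4 / 16)
  expect_equal(unname(as.numeric(pr[c("r1", "r2", "r3", "r4")])), rep(3 / 16, 4))
})

test_that("power-iteration prior agrees with the closed form, including on bipartite graphs", {
  fixtures <- list(triangle_kg(),
                   rand_ring_kg(12, 5, seed = 3),
                   rand_ring_kg(30, 12, seed = 4),
                   # even cycle = bipartite/periodic: lazy walk must still converge
                   kg_from_edges(cbind(sprintf("c%d", 1:6),
                                       sprintf("c%d", c(2:6, 1)))))
  for (g in fixtures) {
    closed <- compute_prior(g, "closed_form")
    power <- compute_prior(g, "power_iteration", tol = 1e-13, max_iter = 50000)
    expect_lt(sum(abs(closed - power)), 1e-8)
  }
  # a non-regular graph cannot converge from the uniform start in one step
  w4 <- kg_from_edges(rbind(c("h", "r1"), c("h", "r2"), c("h", "r3"), c("h", "r4"),
                            c("r1", "r2"), c("r2", "r3"), c("r3", "r4"), c("r4", "r1")))
  expect_error(compute_prior(w4, "power_iteration", tol = 1e-13, max_iter = 2L),
               "did not converge")
})

test_that("posterior solves the restart fixed point: pair graph closed form", {
  pair <- kg_from_edges(rbind(c("s", "t")))
  p <- compute_posterior(pair, "s", restart_prob = 0.25, tol = 1e-14)
  # p_s = c / (1 - (1-c)^2) with c = 0.25
  expect_equal(p[["s"]], 0.25 / (1 - 0.75^2), tolerance = 1e-9)
  expect_equal(p[["t"]], 1 - 0.25 / (1 - 0.75^2), tolerance = 1e-9)
  pe <- solve_posterior_exact(pair, "s", 0.25)
  expect_equal(pe[["s"]], 4 / 7)
  expect_equal(pe[["t"]], 3 / 7)
  expect_error(compute_posterior(pair, "nope"), "unknown source")
})

test_that("restart probability limits: indicator at 1, prior at 0", {
  c4 <- kg_from_edges(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")))
  near1 <- compute_posterior(c4, "a", restart_prob = 0.999, tol = 1e-14)
  expect_gt(near1[["a"]], 0.998)
  # the fixed-point iteration contracts at rate (1 - c), so a vanishing
  # restart needs a proportionally larger iteration budget
  near0 <- compute_posterior(c4, "a", restart_prob = 1e-3, tol = 1e-10,
                             max_iter = 100000L)
  expect_equal(unname(as.numeric(near0)), rep(1 / 4, 4), tolerance = 1e-2)
  expect_error(compute_posterior(c4, "a", restart_prob = 0), "restart_prob")
})

test_that("iterative posterior matches the dense solve and a naive dense oracle", {
  for (seed in 1:6) {
    g <- rand_ring_kg(40, 25, seed = seed)
    src <- kg_ids(g)[5]
    it <- compute_posterior(g, src, tol = 1e-12)
    ex <- solve_posterior_exact(g, src)
    expect_lt(sum(abs(it - ex)), 1e-8)
  }
  g <- rand_ring_kg(10, 4, seed = 9)
  naive <- posterior_oracle_dense(g, "n03")
  ex <- solve_posterior_exact(g, "n03")
  expect_lt(sum(abs(naive - as.numeric(ex[names(naive)]))), 1e-10)
})

test_that("posterior source mass increases with restart probability", {
  g <- rand_ring_kg(20, 8, seed = 11)
  src <- kg_ids(g)[1]
  mass <- vapply(c(0.1, 0.25, 0.5, 0.9), function(c)
    compute_posterior(g, src, restart_prob = c, tol = 1e-12)[[src]], numeric(1))
  expect_true(all(diff(mass) > 0))
})

test_that("posterior is invariant to concept relabeling/permutation", {
  g <- rand_ring_kg(15, 6, seed = 21)
  p1 <- compute_posterior(g, "n05", tol = 1e-12)
  set.seed(42)
  perm <- sample(nrow(g$nodes))
  g2 <- g
  g2$nodes <- g$nodes[perm, ]
  rownames(g2$nodes) <- NULL
  g2 <- knowledge_graph(g2$nodes, g2$relations)
  p2 <- compute_posterior(g2, "n05", tol = 1e-12)
  expect_equal(as.numeric(p2[names(p1)]), as.numeric(p1), tolerance = 1e-10)
})

test_that("on a vertex-transitive cycle the posterior depends only on distance", {
  c6 <- kg_from_edges(cbind(sprintf("c%d", 1:6), sprintf("c%d", c(2:6, 1))))
  p <- compute_posterior(c6, "c1", tol = 1e-13)
  expect_equal(p[["c2"]], p[["c6"]], tolerance = 1e-10)   # distance 1
  expect_equal(p[["c3"]], p[["c5"]], tolerance = 1e-10)   # distance 2
})

test_that("accessibility vectors validate and round-trip through TSV", {
  expect_error(accessibility(c(a = 0.6, b = 0.6), "prior"), "sum to 1")
  expect_error(accessibility(c(a = 1.2, b = -0.2), "prior"), "non-negative")
  expect_error(accessibility(c(a = 0.5, b = 0.5), "posterior"), "source")

  g <- rand_ring_kg(8, 3, seed = 2)
  p <- compute_posterior(g, "n01")
  f <- tempfile(fileext = ".tsv")
  write_accessibility(p, f)
  p2 <- read_accessibility(f)
  expect_equal(as.numeric(p2), as.numeric(p), tolerance = 1e-12)
  expect_equal(attr(p2, "role"), "posterior")
  expect_equal(attr(p2, "source"), "n01")
  expect_equal(attr(p2, "restart_prob"), 0.25)
})
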