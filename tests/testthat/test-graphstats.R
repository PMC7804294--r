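namedGraph <- function(g, prefix = "n") {
  igraph::V(g)$name <- paste0(prefix, seq_len(igraph::vcount(g)))
  g
}

test_that("betweenness on canonical small graphs", {
  path <- igraph::graph_from_literal(a - b - c)
  cc <- centralities(path)
  tab <- cc$table
  expect_equal(tab$betweenness[tab$node == "b"], 1)
  expect_equal(tab$betweenness[tab$node %in% c("a", "c")], c(0, 0))

  star <- namedGraph(igraph::make_star(5, mode = "undirected"))
  cs <- centralities(star)
  expect_true(all(cs$argmax == "n1"))
  expect_equal(max(cs$table$eigenvector), 1)
})

test_that("betweenness matches the exhaustive path-enumeration oracle", {
  set.seed(31)
  for (rep in 1:12) {
    n <- sample(5:8, 1)
    m <- sample(n:(n * (n - 1) / 2), 1)
    g <- igraph::sample_gnm(n, m)
    g <- namedGraph(g)
    cc <- centralities(g, giant = TRUE)
    keep <- match(cc$table$node, paste0("n", seq_len(n)))
    sub <- igraph::induced_subgraph(g, keep)
    expect_equal(cc$table$betweenness, bcOracle(sub), tolerance = 1e-10)
  }
})

test_that("centralities are invariant under node relabelling", {
  set.seed(5)
  g <- namedGraph(igraph::sample_gnm(12, 24))
  cc <- centralities(g, giant = TRUE)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  cc2 <- centralities(g2, giant = TRUE)
  m <- match(cc$table$node, cc2$table$node)
  expect_equal(cc$table$betweenness, cc2$table$betweenness[m],
               tolerance = 1e-10)
  expect_equal(cc$table$eigenvector, cc2$table$eigenvector[m],
               tolerance = 1e-8)
})

test_that("disconnected graphs error unless the giant component is requested", {
  g <- igraph::graph_from_literal(a - b, c - d)
  expect_error(centralities(g), "disconnected")
  cc <- centralities(g, giant = TRUE)
  expect_equal(cc$n_nodes, 2L)
  expect_error(centralities(igraph::make_empty_graph(0)), "empty")
})

test_that("the ER test has the add-one p-value and fixed-seed reproducibility", {
  star <- namedGraph(igraph::make_star(20, mode = "undirected"))
  t1 <- erNullTest(star, nSamples = 999, seed = 3, keepNullSamples = TRUE)
  # no G(20,19) sample reaches the star's maximal betweenness of 1
  expect_equal(t1$results$p[t1$results$statistic == "bc_max"], 1 / 1000)
  expect_true(t1$results$reject[t1$results$statistic == "bc_max"])
  expect_true(t1$coherent_reject)
  expect_equal(length(t1$null_samples$bc_max), 999L)
  # hand-check the formula on the kept null samples
  for (s in t1$results$statistic) {
    obs <- t1$results$observed[t1$results$statistic == s]
    expect_equal(t1$results$p[t1$results$statistic == s],
                 (1 + sum(t1$null_samples[[s]] >= obs)) / 1000)
  }
  t2 <- erNullTest(star, nSamples = 999, seed = 3, keepNullSamples = TRUE)
  expect_identical(t1, t2)
  expect_error(erNullTest(star, nSamples = 50), "100")
})

test_that("the ER test does not disturb the caller's RNG stream", {
  star <- namedGraph(igraph::make_star(10, mode = "undirected"))
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(erNullTest(star, nSamples = 100, seed = 7))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("centrality jumps equal direct subtraction and flag new nodes", {
  g1 <- igraph::graph_from_literal(a - b - c - d)
  g2 <- igraph::graph_from_literal(a - b - c - d - a, a - e)
  c1 <- centralities(g1)
  c2 <- centralities(g2)
  j <- centralityJumps(c1, c2)
  expect_setequal(attr(j, "new_nodes"), "e")
  for (node in intersect(c1$table$node, c2$table$node)) {
    expect_equal(j$d_betweenness[j$node == node],
                 c2$table$betweenness[c2$table$node == node] -
                   c1$table$betweenness[c1$table$node == node])
  }
  jid <- centralityJumps(c1, c1)
  expect_true(all(abs(jid$d_betweenness) < 1e-12))
  expect_true(all(abs(jid$d_eigenvector) < 1e-12))
})

test_that("a node gaining an edge to the hub gains eigenvector centrality", {
  star <- namedGraph(igraph::make_star(8, mode = "undirected"))
  plus <- igraph::add_edges(star, c("n7", "n8"))
  c0 <- centralities(star)
  c1 <- centralities(plus)
  j <- centralityJumps(c0, c1)
  expect_gt(j$d_eigenvector[j$node == "n8"], 0)
})
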