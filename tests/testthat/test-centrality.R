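path3 <- function() igraph::make_graph(~ a - b, b - c)

test_that("degree centrality: raw and normalized conventions", {
  g <- path3()
  raw <- degree_centrality(g, normalized = FALSE)
  expect_equal(unclass(raw)[c("a", "b", "c")], c(a = 1, b = 2, c = 1))
  k4 <- igraph::make_full_graph(4)
  expect_true(all(abs(degree_centrality(k4) - 1) < 1e-12))
  s5 <- igraph::make_star(6, mode = "undirected", center = 1)
  expect_equal(max(degree_centrality(s5, normalized = FALSE)), 5)
})

test_that("closeness centrality follows the inverse-distance-sum form", {
  g <- path3()
  cl <- closeness_centrality(g)
  expect_equal(unname(cl["b"]), 0.5)
  k4 <- igraph::make_full_graph(4)
  expect_true(all(abs(closeness_centrality(k4) - 1 / 3) < 1e-12))
  # two disjoint edges: within-component convention gives 1 everywhere
  g2 <- igraph::make_graph(~ a - b, c - d)
  expect_true(all(abs(closeness_centrality(g2) - 1) < 1e-12))
  # scaled variant down-weights small components
  expect_true(all(abs(closeness_centrality(g2, scaled = TRUE) - 1 / 3) <
                    1e-12))
  # singleton component has closeness 0
  g3 <- igraph::make_empty_graph(1, directed = FALSE)
  expect_equal(unname(as.numeric(closeness_centrality(g3))), 0)
})

test_that("betweenness centrality matches the small worked examples", {
  g <- path3()
  bw <- betweenness_centrality(g)
  expect_equal(unclass(bw)[c("a", "b", "c")], c(a = 0, b = 1, c = 0))
  expect_true(all(betweenness_centrality(igraph::make_full_graph(4)) == 0))
  s4 <- igraph::make_star(5, mode = "undirected", center = 1)
  expect_equal(max(betweenness_centrality(s4)), 1)
})

test_that("closeness and betweenness match the brute-force oracles", {
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(2:8, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.3, 0.8))
    igraph::V(g)$name <- paste0("v", seq_len(n))
    expect_equal(unname(as.numeric(closeness_centrality(g))),
                 oracle_closeness(g), tolerance = 1e-12)
    expect_equal(unname(as.numeric(betweenness_centrality(g))),
                 oracle_betweenness(g), tolerance = 1e-9)
  }
})

test_that("second-order centrality: symmetry, order and the MC oracle", {
  c5 <- igraph::make_ring(5)
  ex <- as.numeric(second_order_exact(c5))
  expect_true(all(abs(ex - ex[1]) < 1e-9))
  # star: center strictly more central (smaller deviation) than leaves
  s4 <- igraph::make_star(5, mode = "undirected", center = 1)
  sv <- as.numeric(second_order_exact(s4))
  expect_lt(sv[1], min(sv[-1]))
  # K2: return times are deterministically 2
  k2 <- igraph::make_full_graph(2)
  expect_true(all(as.numeric(second_order_mc(k2, 2e4, seed = 1)) == 0))
  # same seed -> identical output
  expect_identical(second_order_mc(c5, 2e4, seed = 4),
                   second_order_mc(c5, 2e4, seed = 4))
  # exact vs Monte-Carlo on random connected graphs
  set.seed(32)
  for (rep in 1:2) {
    g <- oracle_random_connected(10)
    ex <- as.numeric(second_order_exact(g))
    mc <- as.numeric(second_order_mc(g, 2e5, seed = rep))
    expect_lt(max(abs(ex - mc) / ex), 0.05)
  }
  # C5 MC estimates within 5% of each other
  mc5 <- as.numeric(second_order_mc(c5, 2e5, seed = 9))
  expect_lt((max(mc5) - min(mc5)) / min(mc5), 0.05)
})

test_that("second-order handles disconnected and bipartite graphs", {
  g <- igraph::disjoint_union(igraph::make_ring(4), igraph::make_ring(3))
  expect_warning(v <- second_order_exact(g), "disconnected")
  expect_true(all(is.finite(as.numeric(v))))
  # bipartite C4: exact finite values, constant by symmetry
  c4 <- igraph::make_ring(4)
  v4 <- as.numeric(second_order_exact(c4))
  expect_true(all(abs(v4 - v4[1]) < 1e-9))
})

test_that("vertex-transitive graphs give constant centralities", {
  for (g in list(igraph::make_ring(6), igraph::make_full_graph(5))) {
    for (ms in c("degree", "closeness", "betweenness", "second_order")) {
      v <- as.numeric(misinfonet:::measure_fun(ms)(g))
      expect_lt(max(v) - min(v), 1e-9)
    }
  }
})

test_that("adding an edge never decreases raw degree centrality", {
  set.seed(33)
  g <- igraph::sample_gnp(8, 0.3)
  if (igraph::are_adjacent(g, 1, 2))
    g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(1, 2)))
  d0 <- as.numeric(degree_centrality(g, normalized = FALSE))
  g2 <- igraph::add_edges(g, c(1, 2))
  d1 <- as.numeric(degree_centrality(g2, normalized = FALSE))
  expect_true(all(d1 >= d0))
})

test_that("centrality series averages per day with gaps for empty days", {
  k4 <- igraph::make_full_graph(4); k2 <- igraph::make_full_graph(2)
  ser <- centrality_series(list(k4, k2), "degree")
  expect_equal(ser$mean, c(1, 1))
  ser2 <- centrality_series(list(k4, igraph::make_empty_graph(0,
                                                              directed = FALSE),
                                 k4), "degree")
  expect_true(is.na(ser2$mean[2]))
  expect_equal(ser2$n, c(4L, 0L, 4L))
  expect_error(centrality_series(list(k4), "pagerank"), "unknown measure")
  expect_error(centrality_series(list(), "degree"), "at least one")
})

test_that("top_k ranks deterministically with lexicographic ties", {
  v <- stats::setNames(c(3, 1, 3, 2), c("zb", "aa", "ab", "cc"))
  expect_equal(top_k(v, 2), c("ab", "zb"))
  expect_equal(top_k(v, 10), c("ab", "zb", "cc", "aa"))
  s4 <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(s4)$name <- c("hub", "l1", "l2", "l3", "l4")
  expect_equal(top_k(degree_centrality(s4), 1), "hub")
  expect_error(top_k(v, 0), "k must")
})
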