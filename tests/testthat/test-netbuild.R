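test_that("cosine_similarity handles the canonical cases and errors", {
  v <- basis_vec(1); w <- basis_vec(2)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, w), 0)
  expect_equal(cosine_similarity(v, -v), -1)
  expect_error(cosine_similarity(v, basis_vec(1, 9)), "dimension")
  expect_error(cosine_similarity(v, numeric(8)), "zero vector")
  expect_error(cosine_similarity(v, 2 * w), "unit")
})

test_that("daily networks partition the stream and threshold strictly", {
  e1 <- basis_vec(1)
  st <- make_toy_stream(c("a", "b", "c", "d", "e"), c(0, 0, 0, 1, 1),
                        rbind(e1, e1, e1, basis_vec(2), basis_vec(3)))
  gs <- build_daily_networks(st, 0.7)
  expect_length(gs, 2)
  expect_equal(igraph::vcount(gs[[1]]), 3)
  expect_equal(igraph::ecount(gs[[1]]), 3)  # identical triple -> triangle
  expect_equal(igraph::vcount(gs[[2]]), 2)
  expect_equal(igraph::ecount(gs[[2]]), 0)  # orthogonal pair
  expect_equal(sum(vapply(gs, igraph::vcount, numeric(1))),
               nrow(st$records))
})

test_that("two zero-dispersion topics give two disjoint cliques", {
  d <- 10
  c1 <- basis_vec(1, d); c2 <- sqrt(c(0.05, 0.95)) # centre similarity ~0.22
  c2 <- c(sqrt(0.05), sqrt(0.95), rep(0, d - 2))
  ids <- sprintf("r%02d", 1:20)
  emb <- rbind(matrix(rep(c1, 10), 10, byrow = TRUE),
               matrix(rep(c2, 10), 10, byrow = TRUE))
  st <- make_toy_stream(ids, rep(0, 20), emb)
  g <- build_daily_networks(st, 0.7)[[1]]
  comp <- igraph::components(g)
  expect_equal(comp$no, 2)
  expect_equal(sort(comp$csize), c(10, 10))
  expect_equal(igraph::ecount(g), 2 * choose(10, 2))
})

test_that("cumulative growth matches the small worked examples", {
  e1 <- basis_vec(1)
  # all-identical embeddings, 1 record/day, 4 days -> K4 at day 3
  st <- make_toy_stream(letters[1:4], 0:3, rbind(e1, e1, e1, e1))
  tg <- grow_cumulative(st, 0.8)
  g <- snapshot(tg, 3)
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), 6)
  # day-1 record matching exactly one day-0 record
  st2 <- make_toy_stream(c("a", "b", "c"), c(0, 0, 1),
                         rbind(e1, basis_vec(2), e1))
  tg2 <- grow_cumulative(st2, 0.8)
  expect_equal(degree_history(tg2, "a")$k, c(0, 1))
  expect_equal(degree_history(tg2, "b")$k, c(0, 0))
  expect_equal(degree_history(tg2, "c")$k, 1)
  # isolated node persists to the final day (no deletion)
  expect_true("b" %in% igraph::V(snapshot(tg2, 1))$name)
})

test_that("growth requires a day-0 base network", {
  st <- make_toy_stream(c("a", "b"), c(1, 2),
                        rbind(basis_vec(1), basis_vec(2)), n_days = 3L)
  expect_error(grow_cumulative(st), "base-network")
  expect_error(grow_with_deletion(st), "base-network")
})

test_that("deletion follows the hand-derived trace exactly", {
  st <- toy_deletion_stream()
  tg <- grow_with_deletion(st, threshold = 0.8, delta = 2)
  nd <- tg$nodes[order(tg$nodes$id), ]
  expect_equal(nd$id, c("a", "b", "c", "d", "e", "f"))
  expect_equal(nd$birth_day, c(0L, 0L, 1L, 1L, 3L, 5L))
  expect_equal(nd$death_day, c(3L, 3L, 3L, 2L, 4L, NA))
  ae <- tg$all_edges
  key <- paste(pmin(ae$from, ae$to), pmax(ae$from, ae$to))
  expect_setequal(key, c("a b", "a c", "b c"))
  expect_equal(ae$creation_day[order(key)], c(0L, 1L, 1L))
  expect_true(all(ae$removal_day == 3L))
  expect_equal(alive_counts(tg), c(2L, 4L, 3L, 1L, 0L, 1L))
  expect_setequal(survivors(tg, 0, 2), c("a", "b"))
  expect_length(survivors(tg, 0, 3), 0)
  # e never connects because d is already dead on day 3
  expect_equal(igraph::ecount(snapshot(tg, 3)), 0)
})

test_that("single isolated day-0 node dies on day delta - 1", {
  st <- make_toy_stream("a", 0, matrix(basis_vec(1), 1), n_days = 6L)
  tg <- grow_with_deletion(st, delta = 3)
  expect_equal(tg$nodes$death_day, 2L)
  # a node gaining an edge every day is never deleted (delta = 2: the
  # birth-day no-gain convention gives an edgeless arrival one day of
  # grace, then a-b, a-c, ... arrive daily)
  e1 <- basis_vec(1)
  st2 <- make_toy_stream(letters[1:5], 0:4, rbind(e1, e1, e1, e1, e1))
  tg2 <- grow_with_deletion(st2, delta = 2)
  expect_true(is.na(tg2$nodes$death_day[tg2$nodes$id == "a"]))
})

test_that("large delta reproduces the no-deletion formulation exactly", {
  for (seed in 1:3) {
    st <- random_small_stream(seed)
    tg2 <- grow_cumulative(st, 0.8)
    tg3 <- grow_with_deletion(st, 0.8, delta = st$config$n_days + 1L)
    expect_identical(tg3$nodes$id, tg2$nodes$id)
    expect_identical(tg3$nodes$death_day, tg2$nodes$death_day)
    expect_identical(tg3$edges, tg2$edges)
    expect_identical(tg3$hist_deg, tg2$hist_deg)
    expect_identical(tg3$hist_gain, tg2$hist_gain)
  }
})

test_that("degree deltas balance edge creations and removals per day", {
  # with degrees extended by zero outside a node's alive span,
  # sum_i dk(i, day) = 2 * created(day) - 2 * removed(day)
  st <- random_small_stream(5)
  tg <- grow_with_deletion(st, 0.8, delta = 2)
  K <- misinfonet:::degree_matrix(tg, "current")
  K[is.na(K)] <- 0
  for (d in 0:tg$current_day) {
    prev <- if (d == 0) rep(0, nrow(K)) else K[, d]
    created <- sum(tg$all_edges$creation_day == d)
    removed <- sum(!is.na(tg$all_edges$removal_day) &
                     tg$all_edges$removal_day == d)
    expect_equal(sum(K[, d + 1] - prev), 2 * created - 2 * removed,
                 info = paste("day", d))
  }
})

test_that("snapshots reconstruct every day consistently", {
  st <- random_small_stream(9)
  tg <- grow_with_deletion(st, 0.8, delta = 2)
  for (d in 0:tg$current_day) {
    g <- snapshot(tg, d)
    ids <- igraph::V(g)$name
    # edges only between co-alive nodes
    if (igraph::ecount(g) > 0) {
      el <- igraph::as_edgelist(g)
      expect_true(all(el %in% ids))
    }
    # degree in snapshot equals hist_deg entry
    for (id in ids) {
      h <- degree_history(tg, id, "current")
      expect_equal(unname(igraph::degree(g)[id]), h$k[h$day == d],
                   info = paste(id, d))
    }
  }
  expect_error(snapshot(tg, tg$current_day + 1L), "range")
  # final snapshot equals the live edge table
  gf <- snapshot(tg, tg$current_day)
  expect_equal(igraph::ecount(gf), nrow(tg$edges))
})

test_that("graph exports are written", {
  st <- random_small_stream(2, n_days = 4)
  tg <- grow_cumulative(st, 0.8)
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  export_edges_tsv(tg, tsv)
  export_graphml(tg, gml)
  expect_equal(nrow(utils::read.delim(tsv)), nrow(tg$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(tg$nodes))
})
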