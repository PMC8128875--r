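# a tiny temporal graph with degrees {a:2, b:1, c:1} on day 1 at
# threshold 0.95: b and c sit on opposite sides of a
tiny_growth <- function() {
  e1 <- basis_vec(1); e2 <- basis_vec(2)
  b <- (e1 + 0.2 * e2) / sqrt(1.04)
  cc <- (e1 - 0.2 * e2) / sqrt(1.04)
  make_toy_stream(c("a", "b", "c"), c(0, 0, 1), rbind(e1, b, cc))
}

test_that("attachment probabilities follow k_i / sum k", {
  tg <- grow_cumulative(tiny_growth(), 0.95)
  ap <- attachment_probability(tg, 1)
  expect_equal(sum(ap$probabilities), 1, tolerance = 1e-12)
  expect_equal(unname(ap$probabilities[c("a", "b", "c")]),
               c(0.5, 0.25, 0.25))
  # regular graph: all equal 1/N
  e1 <- basis_vec(1)
  st <- make_toy_stream(letters[1:4], c(0, 0, 0, 0),
                        rbind(e1, e1, e1, e1))
  tgr <- grow_cumulative(st, 0.8)
  apr <- attachment_probability(tgr, 0)
  expect_true(all(abs(apr$probabilities - 0.25) < 1e-12))
  # edgeless snapshot -> error
  st0 <- make_toy_stream(c("a", "b"), c(0, 0),
                         rbind(basis_vec(1), basis_vec(2)))
  expect_error(attachment_probability(grow_cumulative(st0, 0.8), 0),
               "undefined profile")
})

test_that("PA kernel recovery on simulated growth", {
  tg <- simulate_pa_growth(800, m = 2, alpha = 1, seed = 41)
  pa <- estimate_pa_function(tg)
  expect_gt(pa$alpha, 0.8); expect_lt(pa$alpha, 1.2)
  tg0 <- simulate_pa_growth(800, m = 2, alpha = 0, seed = 42)
  pa0 <- estimate_pa_function(tg0)
  expect_gt(pa0$alpha, -0.2); expect_lt(pa0$alpha, 0.2)
  # normalization contract: A_1 = 1 when degree-1 exposures exist
  st <- random_small_stream(4)
  tgs <- grow_cumulative(st, 0.8)
  pas <- estimate_pa_function(tgs, min_exposures = 1)
  if ("1" %in% names(pas$A_k)) expect_equal(unname(pas$A_k["1"]), 1)
  expect_error(estimate_pa_function(tg, days = 1L), "at least 2 days")
})

test_that("fitness estimation is exact on noiseless histories", {
  h <- 4 * (1:20)^0.5
  fake <- structure(list(
    nodes = data.frame(id = "a", birth_day = 0L, death_day = NA_integer_),
    hist_gain = list(a = c(1, h)), hist_deg = list(a = c(1, h)),
    current_day = 20L), class = "temporal_graph")
  fe <- estimate_fitness(fake, "a")
  expect_equal(fe$beta, 0.5, tolerance = 1e-12)
  expect_equal(fe$offset, log(4), tolerance = 1e-12)
  # constant history -> beta 0
  fake$hist_gain$a <- rep(3, 10)
  expect_equal(estimate_fitness(fake, "a")$beta, 0, tolerance = 1e-12)
  # too short -> error
  fake$hist_gain$a <- c(1, 2)
  expect_error(estimate_fitness(fake, "a"), "insufficient history")
})

test_that("joint PA/fitness estimation recovers nulls and separations", {
  tg <- simulate_pa_growth(600, m = 3, alpha = 1, seed = 51, per_day = 10)
  j <- suppressWarnings(estimate_joint_pa_fitness(tg, max_iter = 150))
  expect_gte(mean(j$fitness >= 0.5 & j$fitness <= 2), 0.9)
  expect_equal(mean(j$fitness[unique(misinfonet:::pa_eventlog(tg)$ex$node)]),
               1, tolerance = 0.05)
  set.seed(52)
  pf <- sample(c(1, 3), 600, replace = TRUE)
  tg2 <- simulate_pa_growth(600, m = 3, alpha = 1, fitness = pf, seed = 53,
                            per_day = 10)
  j2 <- suppressWarnings(estimate_joint_pa_fitness(tg2, max_iter = 150))
  expect_gt(mean(j2$fitness[pf == 3]), mean(j2$fitness[pf == 1]))
  expect_error(estimate_joint_pa_fitness(tg, days = 5L), "at least 2 days")
})

test_that("survivor sets follow birth/death bookkeeping", {
  st <- random_small_stream(6)
  tg2 <- grow_cumulative(st, 0.8)
  d0 <- st$records$id[st$records$day == 0]
  expect_setequal(survivors(tg2, 0, tg2$current_day), d0)
  tg3 <- grow_with_deletion(st, 0.8, delta = 2)
  # nested property: later survivors are a subset of earlier ones
  s_a <- survivors(tg3, 0, 3); s_b <- survivors(tg3, 0, 6)
  expect_true(all(s_b %in% s_a))
  expect_error(survivors(tg3, 5, 3), "require")
})

test_that("cycle detection fires on collapses and stays quiet on growth", {
  st <- random_small_stream(7)
  tg2 <- grow_cumulative(st, 0.8)  # monotone growth
  expect_equal(nrow(detect_cycles(tg2)), 0)
  # scripted collapse and regrowth via a hard topic shift
  sw <- shift_world(n_days = 16, shift_day = 8, seed = 2)
  tg3 <- grow_with_deletion(sw, 0.8, delta = 3)
  ev <- detect_cycles(tg3)
  shr <- ev[ev$kind == "shrink", ]
  expect_gte(nrow(shr), 1)
  expect_true(any(shr$day >= 8 & shr$day <= 12))
  # regrowth past the trough triggers a subsequent expand
  if (any(ev$kind == "expand"))
    expect_gt(min(ev$day[ev$kind == "expand"]),
              min(shr$day))
})

test_that("tfidf matches the hand computation and the brute-force oracle", {
  out <- tfidf_top_terms(list(c("a", "b"), c("a", "c")))
  # hand computation: idf(a)=ln(3/3)+1=1, score 2; others ln(3/2)+1 each
  expect_equal(out$term[1], "a")
  expect_equal(out$score[1], 2)
  expect_equal(out$term[2:5], c("a b", "a c", "b", "c"))
  expect_equal(out$score[2], log(3 / 2) + 1)
  # single document: ranking by raw tf
  one <- tfidf_top_terms(list(c("x", "x", "y")), ngram = 1L)
  expect_equal(one$term, c("x", "y"))
  expect_equal(one$score[1] / one$score[2], 2)
  # rarer term scores higher per occurrence
  two <- tfidf_top_terms(list(c("common", "rare"), c("common")), ngram = 1L)
  expect_gt(two$score[two$term == "rare"] / 1,
            two$score[two$term == "common"] / 2)
  # brute-force agreement on random corpora
  set.seed(61)
  vocab <- letters[1:6]
  for (rep in 1:5) {
    docs <- lapply(seq_len(sample(2:10, 1)), function(i)
      sample(vocab, sample(1:8, 1), replace = TRUE))
    mine <- tfidf_top_terms(docs, top_n = 100)
    orc <- oracle_tfidf(docs, top_n = 100)
    expect_equal(mine$term, orc$term)
    expect_equal(mine$score, orc$score, tolerance = 1e-12)
  }
  expect_error(tfidf_top_terms(list(character(), character())), "empty")
})

test_that("degree histories expose gain and current views", {
  st <- toy_deletion_stream()
  tg <- grow_with_deletion(st, 0.8, delta = 2)
  # node a: edge on day 0 (b), edge on day 1 (c); alive days 0..2
  expect_equal(degree_history(tg, "a", "gain")$k, c(1, 2, 2))
  expect_equal(degree_history(tg, "a", "current")$k, c(1, 2, 2))
  expect_error(degree_history(tg, "zz"), "unknown node")
})
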