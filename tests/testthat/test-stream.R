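test_that("zero-dispersion topics emit the center exactly", {
  cen <- basis_vec(1, 8)
  cfg <- stream_config(3L, list(topic_spec(1L, cen, arrival_rate = 2,
                                           dispersion = 0,
                                           activity_window = c(0L, 2L))),
                       embedding_dim = 8, seed = 4)
  st <- generate_stream(cfg)
  expect_gt(nrow(st$records), 0)
  expect_true(all(abs(st$embeddings %*% cen - 1) < 1e-12))
})

test_that("streams are a pure function of the config seed", {
  cfg1 <- example_stream_config(n_days = 5, embedding_dim = 16,
                                arrival_rate = 4, shift_day = 3, seed = 7)
  cfg2 <- example_stream_config(n_days = 5, embedding_dim = 16,
                                arrival_rate = 4, shift_day = 3, seed = 8)
  s1a <- generate_stream(cfg1); s1b <- generate_stream(cfg1)
  s2 <- generate_stream(cfg2)
  expect_identical(s1a$records, s1b$records)
  expect_identical(s1a$embeddings, s1b$embeddings)
  expect_false(identical(s1a$records$id, s2$records$id) &&
                 identical(s1a$embeddings, s2$embeddings))
})

test_that("activity windows bound record days and population is conserved", {
  cen <- make_topic_centers(2, 12, seed = 2)
  cfg <- stream_config(10L, list(
    topic_spec(1L, cen[1, ], arrival_rate = 5, dispersion = 0.2,
               activity_window = c(0L, 4L)),
    topic_spec(2L, cen[2, ], arrival_rate = 5, dispersion = 0.2,
               activity_window = c(5L, 9L))), embedding_dim = 12, seed = 3)
  st <- generate_stream(cfg)
  expect_true(all(st$records$day[st$records$true_topic == 1] <= 4))
  expect_true(all(st$records$day[st$records$true_topic == 2] >= 5))
  per_day <- table(factor(st$records$day, levels = 0:9))
  expect_equal(sum(per_day), nrow(st$records))
  expect_true(all(abs(rowSums(st$embeddings^2) - 1) < 1e-9))
})

test_that("configuration errors are rejected", {
  expect_error(stream_config(5L, list()), "empty topic")
  cen <- basis_vec(1, 8)
  expect_error(stream_config(5L, list(topic_spec(1L, cen),
                                      topic_spec(2L, basis_vec(1, 9))),
                             embedding_dim = 8), "mismatch")
  expect_error(stream_config(5L, list(topic_spec(1L, cen,
                                                 activity_window = c(2L, 4L))),
                             embedding_dim = 8), "active on day 0")
  expect_error(topic_spec(1L, numeric(8)), "nonzero")
  expect_error(pop_lognormal(sdlog = 0), "sdlog")
  expect_error(pop_powerlaw(alpha = 1), "alpha")
})

test_that("sample_popularity draws from the stated families", {
  # degenerate limit: sdlog -> 0 gives values ~ exp(meanlog)
  v <- sample_popularity(5, pop_lognormal(0, 1e-9), seed = 1)
  expect_true(all(abs(v - 1) < 1e-6))
  # law of large numbers on log scale
  v <- sample_popularity(10000, pop_lognormal(1, 1), seed = 2)
  expect_lt(abs(mean(log(v)) - 1), 0.05)
  # power-law support
  v <- sample_popularity(10000, pop_powerlaw(2.5, 1), seed = 3)
  expect_true(all(v >= 1))
  # determinism
  expect_identical(sample_popularity(50, pop_lognormal(1, 1), seed = 9),
                   sample_popularity(50, pop_lognormal(1, 1), seed = 9))
})

test_that("ground truth reports populations and planted hubs", {
  cen <- make_topic_centers(2, 16, seed = 11)
  cfg <- stream_config(3L, list(
    topic_spec(1L, cen[1, ], arrival_rate = 6, dispersion = 0,
               activity_window = c(0L, 2L)),
    topic_spec(2L, cen[2, ], arrival_rate = 6, dispersion = 0.1,
               activity_window = c(0L, 2L))), embedding_dim = 16, seed = 5)
  st <- generate_stream(cfg)
  gt <- ground_truth(st)
  expect_equal(sum(gt$topic_populations$n), nrow(st$records))
  expect_setequal(unique(gt$membership), c(1L, 2L))
  # dispersion-0 topic: all pairs at cosine similarity 1
  ids1 <- st$records$id[st$records$true_topic == 1]
  s <- st$embeddings[ids1, ] %*% t(st$embeddings[ids1, ])
  expect_true(all(abs(s - 1) < 1e-12))
  # hubs are per day/topic and are real record ids
  expect_true(all(gt$planted_hubs$id %in% st$records$id))
  # cross-topic similarity below within-topic similarity (separated centers)
  ids2 <- st$records$id[st$records$true_topic == 2]
  cross <- st$embeddings[ids1, ] %*% t(st$embeddings[ids2, ])
  within2 <- st$embeddings[ids2, ] %*% t(st$embeddings[ids2, ])
  expect_lt(max(cross), min(within2))
})

test_that("streams without ground truth are rejected by ground_truth", {
  st <- toy_deletion_stream()
  st$records$true_topic <- NULL
  expect_error(ground_truth(st), "unsupported")
})

test_that("within-topic cosine similarity decreases with dispersion", {
  cen <- basis_vec(1, 16)
  mean_sim <- vapply(c(0.1, 0.4, 0.8), function(disp) {
    cfg <- stream_config(2L, list(topic_spec(1L, cen, arrival_rate = 30,
                                             dispersion = disp,
                                             activity_window = c(0L, 1L))),
                         embedding_dim = 16, seed = 21)
    st <- generate_stream(cfg)
    s <- st$embeddings %*% t(st$embeddings)
    mean(s[upper.tri(s)])
  }, numeric(1))
  expect_true(all(diff(mean_sim) < 0))
})

test_that("JSONL round trip preserves the stream and validates cleanly", {
  st <- random_small_stream(3, n_days = 4, dim = 8, rate = 3)
  path <- tempfile(fileext = ".jsonl")
  write_stream_jsonl(st, path)
  v <- validate_stream(path)
  expect_equal(v$n_records, nrow(st$records))
  expect_equal(nrow(v$violations), 0)
  back <- read_stream_jsonl(path)
  expect_equal(back$records$id, st$records$id)
  expect_equal(back$records$day, st$records$day)
  expect_equal(unname(back$embeddings), unname(st$embeddings),
               tolerance = 1e-12)
  # corrupt one embedding -> flagged with its line number
  lines <- readLines(path)
  o <- jsonlite::fromJSON(lines[3])
  o$embedding <- o$embedding * 2
  lines[3] <- as.character(jsonlite::toJSON(o, auto_unbox = TRUE))
  writeLines(lines, path)
  v2 <- validate_stream(path)
  expect_true(any(v2$violations$line == 3 &
                    grepl("non-unit", v2$violations$problem)))
})
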