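# Shared synthetic worlds and hand-built streams for the tests.

# construct a misinfo_stream directly from explicit records
make_toy_stream <- function(ids, days, embeddings, n_days = max(days) + 1L,
                            tokens = NULL, popularity = NULL) {
  embeddings <- as.matrix(embeddings)
  rownames(embeddings) <- ids
  records <- data.frame(id = ids, day = as.integer(days),
                        true_topic = NA_integer_,
                        popularity = if (is.null(popularity)) NA_real_
                        else popularity,
                        category = "toy", stringsAsFactors = FALSE)
  ord <- order(records$day, records$id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  embeddings <- embeddings[records$id, , drop = FALSE]
  if (is.null(tokens))
    tokens <- stats::setNames(rep(list(character()), length(ids)),
                              records$id)
  cfg <- list(n_days = as.integer(n_days),
              embedding_dim = ncol(embeddings), seed = 0L,
              topics = NULL, popularity_model = NULL)
  class(cfg) <- "stream_config"
  structure(list(records = records, embeddings = embeddings,
                 tokens = tokens[records$id], config = cfg),
            class = "misinfo_stream")
}

# orthonormal basis rows for toy embeddings
basis_vec <- function(i, d = 8) { v <- numeric(d); v[i] <- 1; v }

# random small stream for property tests: a few topics, moderate noise
random_small_stream <- function(seed, n_days = 8, dim = 16, rate = 5) {
  cen <- make_topic_centers(2, dim, seed = seed)
  topics <- list(
    topic_spec(1L, cen[1, ], character(), c(0L, n_days - 1L), rate, 0.4),
    topic_spec(2L, cen[2, ], character(), c(0L, n_days - 1L), rate, 0.4))
  generate_stream(stream_config(n_days, topics, embedding_dim = dim,
                                seed = seed))
}

# topic-shift world: early era dies at the shift, background persists
shift_world <- function(n_days = 40, shift_day = 30, dim = 16, seed = 1) {
  cen <- make_topic_centers(3, dim, seed = seed)
  topics <- list(
    topic_spec(1L, cen[1, ], paste0("bg", 1:30), c(0L, n_days - 1L), 8, 0.3),
    topic_spec(2L, cen[2, ], paste0("early", 1:30), c(0L, shift_day - 1L),
               20, 0.3),
    topic_spec(3L, cen[3, ], paste0("late", 1:30),
               c(shift_day, n_days - 1L), 20, 0.3))
  generate_stream(stream_config(n_days, topics, embedding_dim = dim,
                                seed = seed))
}

# the hand-traced 6-record deletion scenario (delta = 2, threshold 0.8):
# a,b day 0 (same direction); c day 1 joins them; d day 1 isolated;
# e day 3 would match d but d is already dead; f day 5 isolated.
toy_deletion_stream <- function() {
  e1 <- basis_vec(1); e2 <- basis_vec(2); e3 <- basis_vec(3)
  make_toy_stream(ids = c("a", "b", "c", "d", "e", "f"),
                  days = c(0, 0, 1, 1, 3, 5),
                  embeddings = rbind(e1, e1, e1, e2, e2, e3),
                  n_days = 6L)
}
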