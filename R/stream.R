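#' @useDynLib misinfonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois rlnorm runif sd coef lm pnorm qnorm dnorm
#'   dlnorm plnorm quantile cor var
#' @importFrom utils head tail write.csv
NULL

# ---------------------------------------------------------------------------
# Synthetic misinformation-record streams.
#
# A stream is a chronologically ordered set of records, each carrying a
# unit-norm embedding drawn around a topic center, optional synthetic tokens,
# and a heavy-tailed popularity count.  Topics switch on and off through hard
# activity windows, which is what produces topic-shift events downstream.
# ---------------------------------------------------------------------------

#' Describe one synthetic topic
#'
#' A topic is a direction in embedding space plus a schedule.  Records of the
#' topic are generated as \code{normalize(center + dispersion * z)} with
#' isotropic Gaussian noise \code{z}, so \code{dispersion = 0} plants records
#' exactly at the center (useful for planted hubs).
#'
#' @param topic_id integer topic label stored in the records' ground truth.
#' @param center numeric vector; normalised internally to unit length.
#' @param vocabulary character vector of tokens records of this topic draw
#'   from; may be empty, in which case records carry no tokens.
#' @param activity_window integer \code{c(start_day, end_day)}, inclusive.
#' @param arrival_rate expected records per active day (Poisson mean).
#' @param dispersion non-negative embedding noise scale.
#' @return an object of class \code{topic_spec}.
#' @export
topic_spec <- function(topic_id, center, vocabulary = character(),
                       activity_window = c(0L, .Machine$integer.max),
                       arrival_rate = 10, dispersion = 0.1) {
  center <- as.numeric(center)
  nrm <- sqrt(sum(center^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("topic center must be a nonzero finite vector")
  if (length(activity_window) != 2L || activity_window[1] > activity_window[2])
    stop("activity_window must be c(start_day, end_day) with start <= end")
  if (arrival_rate < 0) stop("arrival_rate must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  structure(list(
    topic_id = as.integer(topic_id),
    center = center / nrm,
    vocabulary = as.character(vocabulary),
    activity_window = as.integer(activity_window),
    arrival_rate = arrival_rate,
    dispersion = dispersion
  ), class = "topic_spec")
}

#' Popularity models for the stream generator
#'
#' @param meanlog,sdlog log-normal parameters (sdlog > 0).
#' @param alpha,xmin Pareto (continuous power-law) parameters, alpha > 1,
#'   xmin > 0; density \eqn{(\alpha-1)/x_{min} (x/x_{min})^{-\alpha}}.
#' @return a \code{popularity_model} description usable in
#'   \code{\link{stream_config}} and \code{\link{sample_popularity}}.
#' @export
pop_lognormal <- function(meanlog = 1, sdlog = 1) {
  if (sdlog <= 0) stop("sdlog must be > 0")
  structure(list(family = "lognormal", meanlog = meanlog, sdlog = sdlog),
            class = "popularity_model")
}

#' @rdname pop_lognormal
#' @export
pop_powerlaw <- function(alpha = 2.5, xmin = 1) {
  if (alpha <= 1) stop("alpha must be > 1")
  if (xmin <= 0) stop("xmin must be > 0")
  structure(list(family = "powerlaw", alpha = alpha, xmin = xmin),
            class = "popularity_model")
}

#' Configure a synthetic stream
#'
#' @param n_days number of days (>= 1); record days run 0..n_days-1.
#' @param embedding_dim embedding dimension (>= 2).  Defaults to 768, the
#'   width of common sentence-transformer embeddings.
#' @param topics list of \code{\link{topic_spec}} objects sharing
#'   \code{embedding_dim}; at least one must be active on day 0.
#' @param popularity_model a \code{\link{pop_lognormal}} /
#'   \code{\link{pop_powerlaw}} description, or NULL for no popularity field.
#' @param seed integer seed; the stream is a pure function of the config.
#' @return object of class \code{stream_config}.
#' @export
stream_config <- function(n_days, topics, embedding_dim = 768,
                          popularity_model = pop_lognormal(1, 1), seed = 1L) {
  if (n_days < 1) stop("n_days must be >= 1")
  if (embedding_dim < 2) stop("embedding_dim must be >= 2")
  if (length(topics) == 0) stop("configuration error: empty topic list")
  if (inherits(topics, "topic_spec")) topics <- list(topics)
  for (tp in topics) {
    if (!inherits(tp, "topic_spec")) stop("topics must be topic_spec objects")
    if (length(tp$center) != embedding_dim)
      stop("configuration error: embedding_dim mismatch between topics")
  }
  active0 <- vapply(topics, function(tp)
    tp$activity_window[1] <= 0 && tp$activity_window[2] >= 0, logical(1))
  if (!any(active0)) stop("at least one topic must be active on day 0")
  structure(list(
    n_days = as.integer(n_days), embedding_dim = as.integer(embedding_dim),
    topics = topics, popularity_model = popularity_model,
    seed = as.integer(seed)
  ), class = "stream_config")
}

#' Draw popularity counts
#'
#' @param n number of draws (>= 1).
#' @param model a \code{popularity_model}.
#' @param seed integer seed.
#' @return numeric vector of n positive values.
#' @export
sample_popularity <- function(n, model, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  if (!inherits(model, "popularity_model"))
    stop("configuration error: not a popularity_model")
  set.seed(as.integer(seed))
  switch(model$family,
    lognormal = rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog),
    # inverse-CDF Pareto: xmin * u^(-1/(alpha-1))
    powerlaw = model$xmin * runif(n)^(-1 / (model$alpha - 1)),
    stop("unknown popularity family"))
}

#' Generate a synthetic misinformation stream
#'
#' Per day and per active topic the number of arrivals is Poisson with the
#' topic's rate; each record's embedding is the normalised sum of the topic
#' center and isotropic noise, its tokens are draws from the topic
#' vocabulary, and its popularity comes from the configured model.  Records
#' are ordered by (day, id) and ids are zero-padded so lexicographic order
#' equals generation order; the stream is byte-identical under a fixed seed.
#'
#' @param config a \code{\link{stream_config}}.
#' @return object of class \code{misinfo_stream} with elements
#'   \code{records} (data.frame: id, day, true_topic, popularity, category),
#'   \code{embeddings} (matrix, one unit-norm row per record, rownames = id),
#'   \code{tokens} (named list of character vectors) and \code{config}.
#' @export
generate_stream <- function(config) {
  if (!inherits(config, "stream_config")) stop("need a stream_config")
  set.seed(config$seed)
  d <- config$embedding_dim
  rows <- list(); embs <- list(); toks <- list()
  idx <- 0L
  for (day in seq_len(config$n_days) - 1L) {
    for (tp in config$topics) {
      if (day < tp$activity_window[1] || day > tp$activity_window[2]) next
      cnt <- rpois(1L, tp$arrival_rate)
      if (cnt == 0L) next
      for (j in seq_len(cnt)) {
        idx <- idx + 1L
        id <- sprintf("r%03d-%05d", day, idx)
        e <- tp$center
        # noise normalised by sqrt(d) so dispersion sets the expected
        # angular deviation independently of the embedding width:
        # E[cos(e, center)] ~ 1/sqrt(1 + dispersion^2) for any d
        if (tp$dispersion > 0) e <- e + tp$dispersion * rnorm(d) / sqrt(d)
        e <- e / sqrt(sum(e^2))
        rows[[idx]] <- data.frame(
          id = id, day = day, true_topic = tp$topic_id,
          stringsAsFactors = FALSE)
        embs[[idx]] <- e
        toks[[id]] <- if (length(tp$vocabulary))
          sample(tp$vocabulary, 3L + rpois(1L, 5L), replace = TRUE)
        else character()
      }
    }
  }
  if (idx == 0L) stop("configuration produced an empty stream")
  records <- do.call(rbind, rows)
  if (!is.null(config$popularity_model))
    records$popularity <- sample_popularity(idx, config$popularity_model,
                                            seed = config$seed + 1L)
  records$category <- "synthetic"
  ord <- order(records$day, records$id)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  embeddings <- do.call(rbind, embs)[ord, , drop = FALSE]
  rownames(embeddings) <- records$id
  structure(list(records = records, embeddings = embeddings,
                 tokens = toks[records$id], config = config),
            class = "misinfo_stream")
}

#' @export
print.misinfo_stream <- function(x, ...) {
  cat(sprintf("misinfo_stream: %d records over %d days, embedding dim %d\n",
              nrow(x$records), x$config$n_days, ncol(x$embeddings)))
  invisible(x)
}

#' Ground truth of a synthetic stream
#'
#' @param stream a stream produced by \code{\link{generate_stream}}.
#' @return list with \code{topic_populations} (data.frame day, topic, n),
#'   \code{membership} (named topic vector by record id) and
#'   \code{planted_hubs} (data.frame day, topic, id): per day and active
#'   topic, the record with the highest cosine similarity to the topic
#'   center.
#' @export
ground_truth <- function(stream) {
  if (!inherits(stream, "misinfo_stream") ||
      is.null(stream$records$true_topic))
    stop("unsupported input: stream lacks true_topic ground truth")
  rec <- stream$records
  pops <- as.data.frame(table(day = rec$day, topic = rec$true_topic),
                        stringsAsFactors = FALSE)
  pops <- pops[pops$Freq > 0, ]
  pops <- data.frame(day = as.integer(pops$day),
                     topic = as.integer(pops$topic), n = pops$Freq)
  pops <- pops[order(pops$day, pops$topic), ]
  rownames(pops) <- NULL
  centers <- lapply(stream$config$topics, `[[`, "center")
  names(centers) <- vapply(stream$config$topics, function(tp)
    as.character(tp$topic_id), character(1))
  hubs <- list()
  for (day in sort(unique(rec$day))) {
    for (topic in sort(unique(rec$true_topic[rec$day == day]))) {
      ids <- rec$id[rec$day == day & rec$true_topic == topic]
      sims <- stream$embeddings[ids, , drop = FALSE] %*%
        centers[[as.character(topic)]]
      best <- ids[order(-sims, ids)][1]
      hubs[[length(hubs) + 1L]] <- data.frame(
        day = day, topic = topic, id = best, stringsAsFactors = FALSE)
    }
  }
  membership <- stats::setNames(rec$true_topic, rec$id)
  list(topic_populations = pops, membership = membership,
       planted_hubs = do.call(rbind, hubs))
}

#' Serialize / read a stream as JSON-Lines
#'
#' First line is a header object (\code{type:"header"}) echoing dimension,
#' day span and seed; each following line is one record with its embedding
#' as a plain number array.
#'
#' @param stream a \code{misinfo_stream}.
#' @param path file path.
#' @export
write_stream_jsonl <- function(stream, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- list(type = "header", n_days = stream$config$n_days,
              embedding_dim = stream$config$embedding_dim,
              seed = stream$config$seed, n_records = nrow(stream$records))
  writeLines(jsonlite::toJSON(hdr, auto_unbox = TRUE), con)
  rec <- stream$records
  for (i in seq_len(nrow(rec))) {
    obj <- list(id = rec$id[i], day = rec$day[i],
                embedding = as.numeric(stream$embeddings[i, ]),
                tokens = stream$tokens[[rec$id[i]]],
                popularity = rec$popularity[i],
                category = rec$category[i],
                true_topic = rec$true_topic[i])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_stream_jsonl
#' @return \code{read_stream_jsonl}: a \code{misinfo_stream} (config slot
#'   holds only the header echo).
#' @export
read_stream_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("stream file has no records")
  hdr <- jsonlite::fromJSON(lines[1])
  n <- length(lines) - 1L
  ids <- character(n); days <- integer(n); pops <- numeric(n)
  cats <- character(n); tts <- integer(n)
  embs <- matrix(NA_real_, n, hdr$embedding_dim)
  toks <- vector("list", n)
  for (i in seq_len(n)) {
    o <- jsonlite::fromJSON(lines[i + 1L])
    ids[i] <- o$id; days[i] <- o$day
    pops[i] <- if (is.null(o$popularity)) NA_real_ else o$popularity
    cats[i] <- if (is.null(o$category)) NA_character_ else o$category
    tts[i] <- if (is.null(o$true_topic)) NA_integer_ else o$true_topic
    embs[i, ] <- o$embedding
    toks[[i]] <- as.character(o$tokens)
  }
  records <- data.frame(id = ids, day = days, true_topic = tts,
                        popularity = pops, category = cats,
                        stringsAsFactors = FALSE)
  rownames(embs) <- ids
  names(toks) <- ids
  cfg <- list(n_days = hdr$n_days, embedding_dim = hdr$embedding_dim,
              seed = hdr$seed, topics = NULL, popularity_model = NULL)
  class(cfg) <- "stream_config"
  structure(list(records = records, embeddings = embs, tokens = toks,
                 config = cfg), class = "misinfo_stream")
}

#' Well-separated random topic centers
#'
#' Draws unit vectors and orthogonalises them (Gram-Schmidt), giving
#' mutually orthogonal topic centers, the cleanest cluster geometry.
#'
#' @param k number of centers (<= d).
#' @param d embedding dimension.
#' @param seed integer seed.
#' @return k x d matrix of unit rows.
#' @export
make_topic_centers <- function(k, d, seed = 1L) {
  if (k > d) stop("cannot draw more orthogonal centers than dimensions")
  set.seed(as.integer(seed))
  m <- matrix(rnorm(k * d), k, d)
  q <- qr.Q(qr(t(m)))[, seq_len(k), drop = FALSE]
  t(q)
}

#' A planted-hub benchmark stream for the centrality predictor
#'
#' Two well-separated topics, each a diffuse background population
#' (dispersion 2, essentially edgeless at a 0.8 similarity threshold) plus
#' a concentrated hub population (dispersion 0.4) whose records accumulate
#' degree.  With \code{k} around 30 the daily top-k by degree is an
#' embedding-identifiable set, which is what makes the prediction task
#' well-posed: build the daily networks at threshold 0.8.
#'
#' @param n_days days of activity (default 15).
#' @param embedding_dim embedding width (default 24; kept small because the
#'   classifier input follows the stream dimension).
#' @param bg_rate,hub_rate expected background/hub records per topic-day.
#' @param seed integer seed.
#' @return a \code{\link{stream_config}}.
#' @export
planted_hub_config <- function(n_days = 15, embedding_dim = 24,
                               bg_rate = 90, hub_rate = 20, seed = 1L) {
  cen <- make_topic_centers(2, embedding_dim, seed = seed)
  win <- c(0L, n_days - 1L)
  topics <- list(
    topic_spec(1L, cen[1, ], character(), win, bg_rate, 2),
    topic_spec(2L, cen[2, ], character(), win, bg_rate, 2),
    topic_spec(1L, cen[1, ], character(), win, hub_rate, 0.4),
    topic_spec(2L, cen[2, ], character(), win, hub_rate, 0.4))
  stream_config(n_days, topics, embedding_dim = embedding_dim, seed = seed)
}

#' A realistic default stream: three topic eras with a hard shift
#'
#' Emulates roughly two months of daily batches: a persistent background
#' topic, an early-era topic active on days 0..shift_day-1, and a late-era
#' topic taking over from shift_day on.  Each noisy topic is paired with a
#' zero-dispersion "hub" topic at the same center (one hub record expected
#' per day), which plants high-centrality records.
#'
#' @param n_days days of activity (default 60).
#' @param embedding_dim embedding width (default 768).
#' @param arrival_rate expected daily arrivals of each era topic (default
#'   15); the persistent background topic runs at 40% of this so an era's
#'   collapse removes the majority of the deletion network, as in the
#'   reference collapse where almost the whole day-0 base disappeared.
#' @param dispersion embedding noise scale for the noisy topics (default 0.35).
#' @param shift_day day of the hard topic shift (default 30).
#' @param seed integer seed.
#' @return a \code{\link{stream_config}}.
#' @export
example_stream_config <- function(n_days = 60, embedding_dim = 768,
                                  arrival_rate = 15, dispersion = 0.35,
                                  shift_day = 30, seed = 1L) {
  shift_day <- max(1L, min(shift_day, n_days - 1L))
  cen <- make_topic_centers(3, embedding_dim, seed = seed)
  vocab <- function(stub) paste0(stub, seq_len(40))
  topics <- list(
    topic_spec(1L, cen[1, ], vocab("background"), c(0L, n_days - 1L),
               0.4 * arrival_rate, dispersion),
    topic_spec(2L, cen[2, ], vocab("early"), c(0L, shift_day - 1L),
               arrival_rate, dispersion),
    topic_spec(3L, cen[3, ], vocab("late"), c(shift_day, n_days - 1L),
               arrival_rate, dispersion),
    # planted hubs: same centers, zero dispersion, one expected record/day
    topic_spec(1L, cen[1, ], vocab("background"), c(0L, n_days - 1L), 1, 0),
    topic_spec(2L, cen[2, ], vocab("early"), c(0L, shift_day - 1L), 1, 0),
    topic_spec(3L, cen[3, ], vocab("late"), c(shift_day, n_days - 1L), 1, 0)
  )
  stream_config(n_days, topics, embedding_dim = embedding_dim, seed = seed)
}
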