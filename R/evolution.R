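# ---------------------------------------------------------------------------
# Network-evolution analyses on a temporal_graph: per-day attachment
# probabilities, empirical preferential-attachment kernel A_k and its
# log-linear exponent, per-node growth exponents (fitness proxies), a joint
# alternating PA/fitness estimator, survivor sets, shrink-expand cycle
# detection, and TF-IDF top terms for topic-shift summaries.
# ---------------------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

# degree matrix: rows = nodes (tg$nodes order), cols = days 0..current_day;
# D[i, d+1] = degree of node i at end of day d, NA when not alive.
degree_matrix <- function(tg, kind = c("current", "gain")) {
  kind <- match.arg(kind)
  src <- if (kind == "current") tg$hist_deg else tg$hist_gain
  ids <- tg$nodes$id
  D <- matrix(NA_real_, length(ids), tg$current_day + 1L,
              dimnames = list(ids, NULL))
  birth <- tg$nodes$birth_day
  for (i in seq_along(ids)) {
    h <- src[[ids[i]]]
    if (length(h))
      D[i, (birth[i] + 1L):(birth[i] + length(h))] <- h
  }
  D
}

#' Per-node attachment probability on one day
#'
#' The attachment probability of node i is \eqn{k_i / \sum_j k_j} over the
#' nodes alive at the end of the day.  Also reports per-degree mean
#' probabilities and the least-squares line of probability versus degree
#' (for a snapshot this line is exactly linear with slope \eqn{1/\sum k}).
#'
#' @param tg a \code{temporal_graph}.
#' @param day day index.
#' @return object of class \code{attachment_profile}: \code{probabilities}
#'   (named), \code{by_degree} (data.frame k, mean_prob, n), \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{day}.
#' @export
attachment_probability <- function(tg, day) {
  if (day < 0 || day > tg$current_day) stop("day out of range")
  ids <- node_alive_at(tg, day)
  k <- vapply(ids, function(id) {
    h <- tg$hist_deg[[id]]
    h[day - tg$nodes$birth_day[match(id, tg$nodes$id)] + 1L]
  }, numeric(1))
  tot <- sum(k)
  if (tot == 0) stop("undefined profile: snapshot has no edges")
  p <- k / tot
  byk <- stats::aggregate(p, by = list(k = k), FUN = mean)
  names(byk)[2] <- "mean_prob"
  byk$n <- as.integer(table(k)[as.character(byk$k)])
  fit <- lm(p ~ k)
  structure(list(
    probabilities = p, by_degree = byk,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared, day = day
  ), class = "attachment_profile")
}

#' @export
print.attachment_profile <- function(x, ...) {
  cat(sprintf(
    "attachment_profile[day %d]: %d nodes, slope=%.4g, R2=%.3f\n",
    x$day, length(x$probabilities), x$slope, x$r_squared))
  invisible(x)
}

#' @export
print.fitness_estimate <- function(x, ...) {
  cat(sprintf(
    "fitness_estimate[%s]: beta=%.4f, offset=%.4f, R2=%.3f (%d points)\n",
    x$node, x$beta, x$offset, x$r_squared, x$n_points))
  invisible(x)
}

# attachment events and exposures over a day range.  Exposures: one count
# per pre-existing alive node per day with at least one arrival, at the
# degree it held at the end of the previous day.  Events: endpoints of that
# day's new edges that are pre-existing nodes, at the same degree.
pa_eventlog <- function(tg, days = NULL) {
  if (is.null(days)) days <- 1:tg$current_day
  days <- days[days >= 1 & days <= tg$current_day]
  D <- degree_matrix(tg, "current")
  ids <- tg$nodes$id
  birth <- tg$nodes$birth_day
  edges <- if (!is.null(tg$all_edges)) tg$all_edges else tg$edges
  arrival_days <- sort(unique(birth))
  eday <- split(seq_len(nrow(edges)), edges$creation_day)
  evn <- list(); evd <- list(); evk <- list()
  exn <- list(); exd <- list(); exk <- list()
  for (d in days) {
    if (!(d %in% arrival_days)) next
    kprev <- D[, d]  # end of day d-1
    exposed <- which(!is.na(kprev) & birth < d)
    if (!length(exposed)) next
    j <- length(exn) + 1L
    exn[[j]] <- exposed; exd[[j]] <- rep(d, length(exposed))
    exk[[j]] <- kprev[exposed]
    ei <- eday[[as.character(d)]]
    if (length(ei)) {
      ends <- c(edges$from[ei], edges$to[ei])
      old_ends <- ends[birth[match(ends, ids)] < d]
      if (length(old_ends)) {
        oi <- match(old_ends, ids)
        j <- length(evn) + 1L
        evn[[j]] <- oi; evd[[j]] <- rep(d, length(oi)); evk[[j]] <- kprev[oi]
      }
    }
  }
  list(ev = data.frame(node = unlist(evn) %||% integer(),
                       day = unlist(evd) %||% integer(),
                       k = unlist(evk) %||% numeric()),
       ex = data.frame(node = unlist(exn) %||% integer(),
                       day = unlist(exd) %||% integer(),
                       k = unlist(exk) %||% numeric()),
       ids = ids)
}

normalize_kernel <- function(A_k) {
  ks <- as.numeric(names(A_k))
  ref <- if (any(ks == 1 & A_k > 0)) A_k[ks == 1] else {
    pos <- which(A_k > 0)
    if (!length(pos)) stop("empty attachment kernel")
    A_k[pos[1]]
  }
  A_k / ref
}

#' Empirical preferential-attachment kernel and its log-linear exponent
#'
#' The kernel value at degree k is the number of new-edge endpoints landing
#' on pre-existing nodes of degree k divided by the node-day exposures at
#' degree k, normalised so the kernel is 1 at degree 1 (or at the smallest
#' populated degree when no degree-1 exposure exists).  The exponent alpha
#' of the log-linear model \eqn{A_k = k^\alpha} comes from least squares of
#' log A_k on log k over degrees with at least \code{min_exposures}
#' exposures, weighted by attachment counts.
#'
#' @param tg a \code{temporal_graph}.
#' @param days day range to use (default all days after day 0).
#' @param min_exposures minimum exposures for a degree to enter the fit.
#' @return object of class \code{pa_estimate}: \code{A_k} (named by degree),
#'   \code{alpha}, \code{alpha_se}, \code{r_squared}, \code{events},
#'   \code{exposures}.
#' @export
estimate_pa_function <- function(tg, days = NULL, min_exposures = 5L) {
  log_ <- pa_eventlog(tg, days)
  if (nrow(log_$ev) == 0) stop("no new edges in the requested range")
  if (length(unique(log_$ev$day)) < 2)
    stop("need at least 2 days with new edges")
  att <- table(log_$ev$k)
  exs <- table(log_$ex$k)
  ks <- sort(as.numeric(names(exs)))
  A <- vapply(ks, function(k) {
    a <- att[as.character(k)]
    (if (is.na(a)) 0 else as.numeric(a)) / as.numeric(exs[as.character(k)])
  }, numeric(1))
  names(A) <- ks
  A <- normalize_kernel(A)
  usable <- ks >= 1 & as.numeric(exs[as.character(ks)]) >= min_exposures &
    A > 0
  if (sum(usable) < 2) stop("too few usable degrees for the log-linear fit")
  w <- as.numeric(att[as.character(ks[usable])])
  w[is.na(w)] <- 0
  fit <- lm(log(A[usable]) ~ log(ks[usable]), weights = w)
  sm <- suppressWarnings(summary(fit))
  structure(list(A_k = A, alpha = unname(coef(fit)[2]),
                 alpha_se = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 events = nrow(log_$ev), exposures = nrow(log_$ex)),
            class = "pa_estimate")
}

#' @export
print.pa_estimate <- function(x, ...) {
  cat(sprintf("pa_estimate: alpha=%.3f (se %.3f, R2=%.3f), %d events\n",
              x$alpha, x$alpha_se, x$r_squared, x$events))
  invisible(x)
}

#' Growth exponent (fitness proxy) of one node
#'
#' Ordinary least squares of \eqn{\ln k(i,t)} on \eqn{\ln t} over the node's
#' alive span, where t is the node's age in days (t = 1 on the first full
#' day after birth) and k its cumulative gained degree; the slope beta is a
#' linear transform of the node's fitness.  Set \code{time = "absolute"} to
#' fit against absolute day index instead of age.
#'
#' @param tg a \code{temporal_graph}.
#' @param node node id.
#' @param time \code{"age"} (default) or \code{"absolute"}.
#' @param kind degree history to use, \code{"gain"} (default) or
#'   \code{"current"}.
#' @return object of class \code{fitness_estimate}: \code{node},
#'   \code{beta}, \code{offset}, \code{r_squared}, \code{n_points},
#'   \code{window}.
#' @export
estimate_fitness <- function(tg, node, time = c("age", "absolute"),
                             kind = "gain") {
  time <- match.arg(time)
  h <- degree_history(tg, node, kind)
  tt <- if (time == "age") seq_len(nrow(h)) - 1L else h$day
  use <- tt >= 1 & h$k > 0
  if (sum(use) < 3)
    stop("insufficient history: fewer than 3 usable points for ", node)
  lx <- log(tt[use]); ly <- log(h$k[use])
  fit <- lm(ly ~ lx)
  r2 <- if (var(ly) == 0) 1 else suppressWarnings(summary(fit))$r.squared
  structure(list(node = node, beta = unname(coef(fit)[2]),
                 offset = unname(coef(fit)[1]), r_squared = r2,
                 n_points = sum(use),
                 window = range(h$day[use])),
            class = "fitness_estimate")
}

#' Growth exponents for many nodes
#'
#' @param tg a \code{temporal_graph}.
#' @param nodes node ids (default: all with enough history).
#' @param min_points minimum usable history points (default 3).
#' @param ... passed to \code{\link{estimate_fitness}}.
#' @return data.frame: node, beta, offset, r_squared, n_points.
#' @export
fitness_table <- function(tg, nodes = NULL, min_points = 3L, ...) {
  if (is.null(nodes)) nodes <- tg$nodes$id
  rows <- lapply(nodes, function(id) {
    fe <- tryCatch(estimate_fitness(tg, id, ...), error = function(e) NULL)
    if (is.null(fe) || fe$n_points < min_points) return(NULL)
    data.frame(node = id, beta = fe$beta, offset = fe$offset,
               r_squared = fe$r_squared, n_points = fe$n_points,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(node = character(), beta = numeric(),
                      offset = numeric(), r_squared = numeric(),
                      n_points = integer())
  out
}

#' Joint alternating estimation of the PA kernel and node fitness
#'
#' Under the model \eqn{P(\mathrm{attach\ to\ } i) \propto A_{k_i} \eta_i},
#' alternates (i) kernel estimation with each degree's event count divided
#' by the fitness-weighted exposures at that degree and (ii) fitness
#' re-estimation as the shrunk ratio (observed + 1)/(expected + 1) of each
#' node's attachment count to its expectation under the current kernel,
#' with day totals calibrated to the observed totals.  Fitness is rescaled
#' to mean 1 each pass; iteration stops when the maximum relative change
#' drops below \code{tol}.  The +1/+1 shrinkage pulls low-exposure nodes
#' toward fitness 1, without which integer-count noise dominates late-born
#' nodes.
#'
#' @param tg a \code{temporal_graph}.
#' @param days day range (default all days after 0); needs >= 2 days with
#'   new edges.
#' @param max_iter,tol iteration controls (default 50, 1e-4).
#' @param min_exposures degree-filter for the exponent fit.
#' @return list with \code{pa} (a \code{pa_estimate} refitted under the
#'   final fitness weights), \code{fitness} (named by node id),
#'   \code{converged}, \code{iterations}.
#' @export
estimate_joint_pa_fitness <- function(tg, days = NULL, max_iter = 50L,
                                      tol = 1e-4, min_exposures = 5L) {
  log_ <- pa_eventlog(tg, days)
  if (nrow(log_$ev) == 0) stop("no new edges in the requested range")
  if (length(unique(log_$ev$day)) < 2)
    stop("need at least 2 days with new edges")
  ev <- log_$ev; ex <- log_$ex
  n_nodes <- length(log_$ids)
  obs <- numeric(n_nodes)
  tab <- table(ev$node)
  obs[as.integer(names(tab))] <- as.numeric(tab)
  Td <- table(ev$day)              # observed attachments per day
  day_levels <- sort(unique(ex$day))
  Tvec <- as.numeric(Td[as.character(day_levels)])
  Tvec[is.na(Tvec)] <- 0
  day_idx <- match(ex$day, day_levels)
  kmax <- max(ex$k)
  k_idx <- ex$k + 1L               # kernel indexed by degree 0..kmax
  att_k <- numeric(kmax + 1L)
  atab <- table(ev$k)
  att_k[as.numeric(names(atab)) + 1L] <- as.numeric(atab)
  touched <- sort(unique(ex$node))
  eta <- rep(1, n_nodes)
  converged <- FALSE
  iterations <- 0L
  Akern <- NULL
  # log-binned kernel support: degrees 0..9 exact, geometric bins above,
  # so sparse high degrees pool their events instead of yielding one-shot
  # kernel values that the fitness update would then have to absorb.
  degs <- 0:kmax
  bin_of <- integer(kmax + 1L)
  bin_of[degs <= 9] <- degs[degs <= 9] + 1L
  if (kmax > 9)
    bin_of[degs > 9] <- 10L + findInterval(log(degs[degs > 9] / 10),
                                           log(1.25) * (0:200)) + 1L
  ev_bin <- bin_of[ev$k + 1L]
  ex_bin <- bin_of[k_idx]
  n_exp_bin <- tabulate(ex_bin)
  for (it in seq_len(max_iter)) {
    iterations <- it
    # (i) kernel: events weighted by 1/eta of the receiver, per exposure
    wev <- rowsum(1 / eta[ev$node], ev_bin)
    Abin <- numeric(max(ex_bin))
    bi <- as.integer(rownames(wev))
    Abin[bi] <- wev[, 1] / pmax(n_exp_bin[bi], 1L)
    Akern <- Abin[bin_of]
    # (ii) fitness: expected counts with day totals calibrated
    Av <- Akern[k_idx]
    w <- Av * eta[ex$node]
    denom_d <- rowsum(w, day_idx)[, 1]
    lam <- ifelse(denom_d > 0, Tvec[as.integer(names(denom_d))] /
                    denom_d, 0)
    expd <- rowsum(Av * lam[match(day_idx, as.integer(names(denom_d)))],
                   ex$node)
    expected <- numeric(n_nodes)
    expected[as.integer(rownames(expd))] <- expd[, 1]
    # empirical-Bayes shrinkage: eta ~ Gamma(c, c) with the prior strength
    # c set by the Gamma-Poisson moment identity Var(obs) = e + e^2 Var(eta)
    # on the touched nodes.  A homogeneous world shows no overdispersion,
    # so c grows large and every eta collapses to 1; genuinely heterogeneous
    # fitness keeps its spread.
    e_t <- expected[touched]; o_t <- obs[touched]
    v_eta <- sum((o_t - e_t)^2 - e_t) / max(sum(e_t^2), 1e-12)
    c_prior <- 1 / max(v_eta, 1e-4)
    c_prior <- min(max(c_prior, 1), 1e6)
    cand <- eta
    cand[touched] <- (o_t + c_prior) / (e_t + c_prior)
    # half-step in log space damps the slow A_k <-> eta trade-off drift
    eta_new <- eta
    eta_new[touched] <- sqrt(eta[touched] * cand[touched])
    eta_new[touched] <- eta_new[touched] / mean(eta_new[touched])
    delta <- max(abs(eta_new - eta) / pmax(eta, 1e-12))
    eta <- eta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  # final kernel, normalised, plus log-linear exponent
  ks <- 0:kmax
  have <- tabulate(k_idx, nbins = kmax + 1L) > 0
  A <- Akern[have]
  names(A) <- ks[have]
  A <- normalize_kernel(A)
  ksv <- as.numeric(names(A))
  expos <- tabulate(k_idx, nbins = kmax + 1L)[have]
  usable <- ksv >= 1 & expos >= min_exposures & A > 0
  pa <- NULL
  if (sum(usable) >= 2) {
    wts <- att_k[have][usable]
    fit <- lm(log(A[usable]) ~ log(ksv[usable]), weights = wts)
    sm <- suppressWarnings(summary(fit))
    pa <- structure(list(A_k = A, alpha = unname(coef(fit)[2]),
                         alpha_se = sm$coefficients[2, 2],
                         r_squared = sm$r.squared,
                         events = nrow(ev), exposures = nrow(ex)),
                    class = "pa_estimate")
  }
  fitness <- stats::setNames(eta, log_$ids)
  if (!converged)
    warning("joint PA/fitness estimation did not converge after ",
            max_iter, " iterations (last max relative change > tol)")
  list(pa = pa, fitness = fitness, converged = converged,
       iterations = iterations)
}

#' Survivor set: nodes born on one day still alive at a later day
#'
#' @param tg a \code{temporal_graph}.
#' @param born_day birth day.
#' @param through_day day the nodes must still be alive at the end of.
#' @return character vector of node ids.
#' @export
survivors <- function(tg, born_day, through_day) {
  if (born_day > through_day || through_day > tg$current_day ||
      born_day < 0)
    stop("require 0 <= born_day <= through_day <= current_day")
  with(tg$nodes, id[birth_day == born_day &
                      (is.na(death_day) | death_day > through_day)])
}

#' Detect shrink-expand cycles in the alive-node count
#'
#' A shrink event fires when the alive-node count falls by at least
#' \code{drop_frac} relative to the maximum over the trailing
#' \code{window} days; after a shrink, an expand event fires when the count
#' recovers by the symmetric relative amount above the post-shrink trough.
#'
#' @param tg a \code{temporal_graph} with >= 3 days of history.
#' @param drop_frac relative change threshold (default 0.5).
#' @param window trailing-maximum window in days (default 2).
#' @return data.frame of events: kind ("shrink"/"expand"), day,
#'   relative_change; zero rows when the series is quiet.
#' @export
detect_cycles <- function(tg, drop_frac = 0.5, window = 2L) {
  counts <- alive_counts(tg)
  if (length(counts) < 3) stop("need at least 3 days of history")
  events <- list()
  state <- "normal"; trough <- NA_real_
  for (d in seq_along(counts)[-1]) {
    if (state == "normal") {
      lo <- max(1L, d - window)
      M <- max(counts[lo:(d - 1L)])
      if (M > 0 && counts[d] <= (1 - drop_frac) * M) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "shrink", day = d - 1L,
          relative_change = (counts[d] - M) / M)
        state <- "contracted"; trough <- counts[d]
      }
    } else {
      trough <- min(trough, counts[d])
      if (counts[d] >= trough / (1 - drop_frac) && counts[d] > trough) {
        events[[length(events) + 1L]] <- data.frame(
          kind = "expand", day = d - 1L,
          relative_change = (counts[d] - trough) / max(trough, 1))
        state <- "normal"
      }
    }
  }
  if (!length(events))
    return(data.frame(kind = character(), day = integer(),
                      relative_change = numeric()))
  out <- do.call(rbind, events)
  rownames(out) <- NULL
  out
}

# n-gram expansion of one token vector
ngram_terms <- function(tokens, ngram = c(1L, 2L)) {
  out <- character(0)
  for (n in ngram) {
    if (length(tokens) < n) next
    if (n == 1L) out <- c(out, tokens)
    else {
      idx <- seq_len(length(tokens) - n + 1L)
      grams <- tokens[idx]
      for (j in seq_len(n - 1L)) grams <- paste(grams, tokens[idx + j])
      out <- c(out, grams)
    }
  }
  out
}

#' TF-IDF top terms of a token corpus
#'
#' Terms are unigrams and bigrams by default.  Term frequency is the raw
#' in-document count; idf is smoothed, \eqn{\ln((1+N)/(1+df)) + 1}; the
#' corpus score of a term is the sum over documents of tf * idf.  Ties are
#' broken lexicographically.
#'
#' @param docs list of character token vectors; at least one nonempty.
#' @param ngram n-gram sizes (default \code{c(1, 2)}).
#' @param top_n number of terms to return (default 30).
#' @return data.frame: term, score, df; at most \code{top_n} rows,
#'   descending score.
#' @export
tfidf_top_terms <- function(docs, ngram = c(1L, 2L), top_n = 30L) {
  docs <- lapply(docs, as.character)
  if (!length(docs) || all(lengths(docs) == 0))
    stop("all documents are empty")
  N <- length(docs)
  per_doc <- lapply(docs, function(d) {
    tms <- ngram_terms(d, ngram)
    if (!length(tms)) return(NULL)
    table(tms)
  })
  terms <- sort(unique(unlist(lapply(per_doc, names))))
  tf_total <- numeric(length(terms)); names(tf_total) <- terms
  df <- numeric(length(terms)); names(df) <- terms
  for (tab in per_doc) {
    if (is.null(tab)) next
    tf_total[names(tab)] <- tf_total[names(tab)] + as.numeric(tab)
    df[names(tab)] <- df[names(tab)] + 1
  }
  idf <- log((1 + N) / (1 + df)) + 1
  score <- tf_total * idf       # sum over docs of tf*idf = idf * total tf
  ord <- order(-score, terms)
  out <- data.frame(term = terms[ord], score = unname(score[ord]),
                    df = as.integer(unname(df[ord])),
                    stringsAsFactors = FALSE)
  head(out, top_n)
}

#' Simulate preferential-attachment growth with optional node fitness
#'
#' Grows a network one node per day from an initial clique.  Each arriving
#' node links to \code{m} distinct existing nodes chosen with probability
#' proportional to \eqn{k^\alpha \eta}; \code{alpha = 1, fitness = NULL}
#' is the linear Barabasi-Albert model, \code{alpha = 0} uniform
#' attachment, and a non-constant \code{fitness} vector the
#' Bianconi-Barabasi fitness model.  Returns a \code{temporal_graph}, so
#' the growth can be fed to the same estimators as a record stream.
#'
#' @param n_nodes total nodes including the seed clique.
#' @param m edges per arriving node (default 2).
#' @param alpha kernel exponent used by the generator (default 1).
#' @param fitness optional per-node multiplicative fitness, length
#'   \code{n_nodes}.
#' @param seed integer seed.
#' @param m0 seed-clique size (default \code{m + 1}).
#' @param per_day arriving nodes per day (default 1); batch arrivals mimic
#'   a daily stream, letting long-lived nodes accumulate many edges per day.
#' @return a \code{temporal_graph} with attribute \code{"fitness"}.
#' @export
simulate_pa_growth <- function(n_nodes, m = 2L, alpha = 1, fitness = NULL,
                               seed = 1L, m0 = m + 1L, per_day = 1L) {
  if (n_nodes <= m0) stop("n_nodes must exceed the seed clique size")
  if (is.null(fitness)) fitness <- rep(1, n_nodes)
  if (length(fitness) != n_nodes) stop("fitness must have length n_nodes")
  set.seed(as.integer(seed))
  ids <- sprintf("n%05d", seq_len(n_nodes))
  n_arrivals <- n_nodes - m0
  n_days <- as.integer(ceiling(n_arrivals / per_day)) + 1L
  deg <- numeric(n_nodes)
  D <- matrix(NA_real_, n_nodes, n_days)
  birth <- c(rep(0L, m0),
             rep(seq_len(n_days - 1L), each = per_day)[seq_len(n_arrivals)])
  seed_pairs <- utils::combn(m0, 2)
  ef <- ids[seed_pairs[1, ]]; et <- ids[seed_pairs[2, ]]
  ed <- rep(0L, ncol(seed_pairs))
  deg[1:m0] <- m0 - 1
  D[1:m0, 1] <- deg[1:m0]
  existing <- m0
  for (new in (m0 + 1L):n_nodes) {
    day <- birth[new]
    w <- (deg[1:existing]^alpha) * fitness[1:existing]
    if (all(w == 0)) w <- rep(1, existing)
    mm <- min(m, existing)
    targets <- sample.int(existing, mm, prob = w)
    ef <- c(ef, rep(ids[new], mm)); et <- c(et, ids[targets])
    ed <- c(ed, rep(day, mm))
    deg[targets] <- deg[targets] + 1
    deg[new] <- mm
    existing <- new
    if (new == n_nodes || birth[new + 1L] > day)
      D[1:existing, day + 1L] <- deg[1:existing]
  }
  hist <- lapply(seq_len(n_nodes), function(i) {
    h <- D[i, !is.na(D[i, ])]
    as.numeric(h)
  })
  names(hist) <- ids
  nodes <- data.frame(id = ids, birth_day = birth,
                      death_day = NA_integer_, stringsAsFactors = FALSE)
  all_edges <- data.frame(from = ef, to = et, creation_day = ed,
                          removal_day = NA_integer_,
                          stringsAsFactors = FALSE)
  tg <- structure(list(
    nodes = nodes,
    edges = all_edges[, c("from", "to", "creation_day")],
    all_edges = all_edges,
    hist_deg = hist, hist_gain = hist,
    current_day = n_days - 1L, n_days = n_days,
    threshold = NA_real_, delta = Inf
  ), class = "temporal_graph")
  attr(tg, "fitness") <- stats::setNames(fitness, ids)
  tg
}
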