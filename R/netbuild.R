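# ---------------------------------------------------------------------------
# Three similarity-network formulations over a record stream:
#   I   one static graph per day (cosine similarity > 0.7 by default);
#   II  cumulative growth from the day-0 base network (> 0.8);
#   III cumulative growth plus a delta-consecutive-day deletion rule.
# The temporal_graph container keeps full provenance: per-node birth/death
# days, per-edge creation days, and two per-node degree histories (current
# degree and cumulative edges-ever-gained), from which any daily snapshot is
# reconstructable exactly.
# ---------------------------------------------------------------------------

#' Cosine similarity of two unit vectors
#'
#' @param u,v numeric vectors of equal length and unit norm (1e-6 tolerance).
#' @return their dot product, in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero vector has no direction")
  if (abs(nu - 1) > 1e-6 || abs(nv - 1) > 1e-6)
    stop("inputs must be unit vectors")
  sum(u * v)
}

# edge pairs (strict >) within one embedding block; returns two id vectors
intra_edges <- function(emb, threshold) {
  if (nrow(emb) < 2) return(list(from = character(), to = character()))
  s <- emb %*% t(emb)
  idx <- which(upper.tri(s) & s > threshold, arr.ind = TRUE)
  list(from = rownames(emb)[idx[, 1]], to = rownames(emb)[idx[, 2]])
}

# edge pairs between new block and existing block
cross_edges <- function(emb_new, emb_old, threshold) {
  if (nrow(emb_new) == 0 || nrow(emb_old) == 0)
    return(list(from = character(), to = character()))
  s <- emb_new %*% t(emb_old)
  idx <- which(s > threshold, arr.ind = TRUE)
  list(from = rownames(emb_new)[idx[, 1]], to = rownames(emb_old)[idx[, 2]])
}

#' Formulation I: one similarity network per day
#'
#' The day-t graph contains exactly the records with day = t; two records are
#' linked when their cosine similarity strictly exceeds the threshold.  Days
#' without records yield empty graphs, so the graphs partition the stream.
#'
#' @param stream a \code{misinfo_stream}.
#' @param threshold similarity threshold in (0,1); default 0.7.
#' @return list of igraph objects, one per day 0..n_days-1, named by day.
#' @export
build_daily_networks <- function(stream, threshold = 0.7) {
  if (!inherits(stream, "misinfo_stream")) stop("need a misinfo_stream")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  n_days <- stream$config$n_days
  if (is.null(n_days)) n_days <- max(stream$records$day) + 1L
  out <- vector("list", n_days)
  for (day in seq_len(n_days) - 1L) {
    ids <- stream$records$id[stream$records$day == day]
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    if (length(ids)) {
      g <- igraph::add_vertices(g, length(ids), name = ids)
      e <- intra_edges(stream$embeddings[ids, , drop = FALSE], threshold)
      if (length(e$from))
        g <- igraph::add_edges(g, rbind(e$from, e$to))
    }
    out[[day + 1L]] <- g
  }
  names(out) <- as.character(seq_len(n_days) - 1L)
  out
}

# shared growth engine; delta = Inf reproduces the no-deletion formulation
grow_engine <- function(stream, threshold, delta) {
  if (!inherits(stream, "misinfo_stream")) stop("need a misinfo_stream")
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  if (!is.infinite(delta) && delta < 1)
    stop("configuration error: delta must be >= 1")
  rec <- stream$records
  if (!any(rec$day == 0))
    stop("base-network error: stream has no records on day 0")
  n_days <- stream$config$n_days
  if (is.null(n_days)) n_days <- max(rec$day) + 1L

  birth <- integer(0); names(birth) <- character(0)
  death <- integer(0)
  last_gain <- integer(0)
  deg <- integer(0)
  gain <- integer(0)
  henv_deg <- new.env(parent = emptyenv())
  henv_gain <- new.env(parent = emptyenv())
  edges_from <- character(0); edges_to <- character(0)
  edges_day <- integer(0); edges_removed <- integer(0)
  alive <- character(0)

  for (day in seq_len(n_days) - 1L) {
    new_ids <- rec$id[rec$day == day]
    gained_today <- character(0)
    if (length(new_ids)) {
      emb_new <- stream$embeddings[new_ids, , drop = FALSE]
      ce <- cross_edges(emb_new, stream$embeddings[alive, , drop = FALSE],
                        threshold)
      ie <- intra_edges(emb_new, threshold)
      ef <- c(ce$from, ie$from); et <- c(ce$to, ie$to)
      birth[new_ids] <- day
      deg[new_ids] <- 0L; gain[new_ids] <- 0L
      last_gain[new_ids] <- day - 1L  # edgeless arrival: birth day counts
      alive <- c(alive, new_ids)
      for (id in new_ids) {
        henv_deg[[id]] <- integer(0); henv_gain[[id]] <- integer(0)
      }
      if (length(ef)) {
        edges_from <- c(edges_from, ef); edges_to <- c(edges_to, et)
        edges_day <- c(edges_day, rep(day, length(ef)))
        edges_removed <- c(edges_removed, rep(NA_integer_, length(ef)))
        dtab <- table(c(ef, et))
        deg[names(dtab)] <- deg[names(dtab)] + as.integer(dtab)
        gain[names(dtab)] <- gain[names(dtab)] + as.integer(dtab)
        gained_today <- names(dtab)
      }
    }
    last_gain[gained_today] <- day
    # deletion sweep: simultaneous, after the day's insertions
    if (!is.infinite(delta) && length(alive)) {
      dead <- alive[day - last_gain[alive] >= delta]
      if (length(dead)) {
        death[dead] <- day
        hit <- is.na(edges_removed) &
          (edges_from %in% dead | edges_to %in% dead)
        if (any(hit)) {
          dtab <- table(c(edges_from[hit], edges_to[hit]))
          deg[names(dtab)] <- deg[names(dtab)] - as.integer(dtab)
          edges_removed[hit] <- day
        }
        alive <- setdiff(alive, dead)
      }
    }
    for (id in alive) {
      henv_deg[[id]] <- c(henv_deg[[id]], deg[[id]])
      henv_gain[[id]] <- c(henv_gain[[id]], gain[[id]])
    }
  }
  ids <- names(birth)
  nodes <- data.frame(id = ids, birth_day = unname(birth[ids]),
                      death_day = ifelse(ids %in% names(death),
                                         unname(death[ids]), NA_integer_),
                      stringsAsFactors = FALSE)
  all_edges <- data.frame(from = edges_from, to = edges_to,
                          creation_day = edges_day,
                          removal_day = edges_removed,
                          stringsAsFactors = FALSE)
  structure(list(
    nodes = nodes,
    edges = all_edges[is.na(all_edges$removal_day),
                      c("from", "to", "creation_day")],
    all_edges = all_edges,
    hist_deg = as.list(henv_deg), hist_gain = as.list(henv_gain),
    current_day = n_days - 1L, n_days = n_days,
    threshold = threshold, delta = delta
  ), class = "temporal_graph")
}

#' Formulation II: cumulative growth without deletion
#'
#' Day-0 records form the base network; each later day's records join as
#' nodes with edges to every node already present (including earlier
#' same-day arrivals) whose similarity strictly exceeds the threshold.
#'
#' @param stream a \code{misinfo_stream} with at least one day-0 record.
#' @param threshold similarity threshold in (0,1); default 0.8.
#' @return a \code{temporal_graph}.
#' @export
grow_cumulative <- function(stream, threshold = 0.8) {
  grow_engine(stream, threshold, Inf)
}

#' Formulation III: cumulative growth with consecutive-day node deletion
#'
#' As \code{\link{grow_cumulative}}, but after each day's insertions any
#' alive node that has gained no new edge on each of the last \code{delta}
#' consecutive days is removed together with all its edges.  A node arriving
#' with zero edges starts its no-gain window on its birth day, so an
#' isolated day-0 node with \code{delta = 3} dies on day 2.  Removal is
#' simultaneous (one sweep per day, computed before any removal is applied).
#'
#' @param stream a \code{misinfo_stream} with at least one day-0 record.
#' @param threshold similarity threshold in (0,1); default 0.8.
#' @param delta consecutive no-gain days before removal (>= 1); default 3.
#' @return a \code{temporal_graph}; the \code{edges} table holds edges still
#'   present at the final day, \code{all_edges} every edge ever created.
#' @export
grow_with_deletion <- function(stream, threshold = 0.8, delta = 3L) {
  tg <- grow_engine(stream, threshold, delta)
  tg
}

#' @export
print.temporal_graph <- function(x, ...) {
  alive <- sum(is.na(x$nodes$death_day) | x$nodes$death_day > x$current_day)
  cat(sprintf(
    "temporal_graph: %d nodes ever (%d alive), %d live edges, day %d%s\n",
    nrow(x$nodes), alive, nrow(x$edges), x$current_day,
    if (is.infinite(x$delta)) "" else sprintf(", delta=%d", x$delta)))
  invisible(x)
}

node_alive_at <- function(tg, day) {
  with(tg$nodes, id[birth_day <= day & (is.na(death_day) | death_day > day)])
}

#' Reconstruct the static graph alive at the end of a day
#'
#' @param tg a \code{temporal_graph}.
#' @param day integer in 0..current_day.
#' @return an igraph with the nodes and edges alive at end of \code{day};
#'   node attribute \code{birth_day}, edge attribute \code{creation_day}.
#' @export
snapshot <- function(tg, day) {
  if (day < 0 || day > tg$current_day) stop("day out of range")
  ids <- node_alive_at(tg, day)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  if (!length(ids)) return(g)
  birth <- tg$nodes$birth_day[match(ids, tg$nodes$id)]
  g <- igraph::add_vertices(g, length(ids), name = ids, birth_day = birth)
  e <- tg$all_edges
  keep <- e$creation_day <= day &
    (is.na(e$removal_day) | e$removal_day > day)
  if (any(keep))
    g <- igraph::add_edges(g, rbind(e$from[keep], e$to[keep]),
                           creation_day = e$creation_day[keep])
  g
}

#' Alive-node count per day
#'
#' @param tg a \code{temporal_graph}.
#' @return integer vector indexed by day 0..current_day.
#' @export
alive_counts <- function(tg) {
  vapply(0:tg$current_day, function(d) length(node_alive_at(tg, d)),
         integer(1))
}

#' Export the live edge list with creation days as TSV
#'
#' @param tg a \code{temporal_graph}.
#' @param path output file.
#' @export
export_edges_tsv <- function(tg, path) {
  utils::write.table(tg$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a temporal graph as GraphML with birth/death attributes
#'
#' @param tg a \code{temporal_graph}.
#' @param path output file.
#' @export
export_graphml <- function(tg, path) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(tg$nodes), name = tg$nodes$id,
                            birth_day = tg$nodes$birth_day,
                            death_day = ifelse(is.na(tg$nodes$death_day),
                                               -1L, tg$nodes$death_day))
  if (nrow(tg$edges))
    g <- igraph::add_edges(g, rbind(tg$edges$from, tg$edges$to),
                           creation_day = tg$edges$creation_day)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Degree history of one node
#'
#' @param tg a \code{temporal_graph}.
#' @param id node id.
#' @param kind \code{"gain"} for the cumulative count of edges ever attached
#'   (non-decreasing; the growth-curve input for fitness estimation) or
#'   \code{"current"} for the live degree (can drop when neighbours die).
#' @return data.frame with columns day and k, one row per alive day.
#' @export
degree_history <- function(tg, id, kind = c("gain", "current")) {
  kind <- match.arg(kind)
  h <- if (kind == "gain") tg$hist_gain[[id]] else tg$hist_deg[[id]]
  if (is.null(h)) stop("unknown node id: ", id)
  birth <- tg$nodes$birth_day[match(id, tg$nodes$id)]
  data.frame(day = birth + seq_along(h) - 1L, k = h)
}
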