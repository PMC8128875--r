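# ---------------------------------------------------------------------------
# Node centralities: degree, closeness (within connected components),
# shortest-path betweenness, and second-order centrality -- the standard
# deviation of the return times of a perpetual uniform random walk, computed
# exactly from first-return-time moments or estimated from one long walk.
# ---------------------------------------------------------------------------

cvec <- function(values, measure, normalized = FALSE) {
  structure(values, measure = measure, normalized = normalized,
            class = c("centrality_vector", "numeric"))
}

#' @export
print.centrality_vector <- function(x, ...) {
  cat(sprintf("centrality_vector[%s%s], %d nodes\n", attr(x, "measure"),
              if (isTRUE(attr(x, "normalized"))) ", normalized" else "",
              length(x)))
  print(unclass(x), ...)
  invisible(x)
}

graph_names <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) as.character(seq_len(igraph::vcount(g))) else nm
}

#' Degree centrality
#'
#' Raw form is the plain degree deg(n); the normalised form divides by N-1.
#'
#' @param g an undirected igraph.
#' @param normalized divide by N-1 (default TRUE).
#' @return named \code{centrality_vector}.
#' @export
degree_centrality <- function(g, normalized = TRUE) {
  n <- igraph::vcount(g)
  v <- as.numeric(igraph::degree(g))
  if (normalized && n >= 2) v <- v / (n - 1)
  cvec(stats::setNames(v, graph_names(g)), "degree", normalized)
}

#' Closeness centrality (within connected components)
#'
#' For each node, the reciprocal of the sum of shortest-path distances to
#' the nodes reachable from it; isolated nodes get 0.  With
#' \code{scaled = TRUE} the value is multiplied by (r-1)/(N-1), r the size
#' of the node's component (Wasserman-Faust), making values comparable
#' across graphs with several components.
#'
#' @param g an undirected igraph.
#' @param scaled apply the component-size scaling (default FALSE).
#' @return named \code{centrality_vector}.
#' @export
closeness_centrality <- function(g, scaled = FALSE) {
  n <- igraph::vcount(g)
  nm <- graph_names(g)
  if (n == 0) return(cvec(stats::setNames(numeric(0), character(0)),
                          "closeness", scaled))
  d <- igraph::distances(g)
  comp <- igraph::components(g)
  v <- numeric(n)
  for (i in seq_len(n)) {
    reach <- which(comp$membership == comp$membership[i])
    reach <- setdiff(reach, i)
    if (!length(reach)) { v[i] <- 0; next }
    v[i] <- 1 / sum(d[i, reach])
    if (scaled && n >= 2) v[i] <- v[i] * length(reach) / (n - 1)
  }
  cvec(stats::setNames(v, nm), "closeness", scaled)
}

#' Shortest-path betweenness centrality
#'
#' @param g an undirected igraph.
#' @param normalized divide by (N-1)(N-2)/2 (default TRUE).
#' @return named \code{centrality_vector}.
#' @export
betweenness_centrality <- function(g, normalized = TRUE) {
  n <- igraph::vcount(g)
  v <- as.numeric(igraph::betweenness(g, directed = FALSE))
  if (normalized && n >= 3) v <- v / ((n - 1) * (n - 2) / 2)
  cvec(stats::setNames(v, graph_names(g)), "betweenness", normalized)
}

# first-return-time mean and sd for the uniform random walk on one
# connected component, by first-step analysis: with h_j = E_j[T_i] and
# s_j = E_j[T_i^2] (hitting i from j), h and s solve linear systems with
# absorbing boundary at i; the return moments condition on the first step.
second_order_component <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  P <- A / deg
  out <- numeric(n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    Q <- P[keep, keep, drop = FALSE]
    M <- diag(length(keep)) - Q
    h <- solve(M, rep(1, length(keep)))
    s <- solve(M, 1 + 2 * (Q %*% h))
    hf <- numeric(n); hf[keep] <- h
    sf <- numeric(n); sf[keep] <- s
    m1 <- 1 + sum(P[i, ] * hf)
    m2 <- 1 + sum(P[i, ] * (2 * hf + sf))
    out[i] <- sqrt(max(m2 - m1^2, 0))
  }
  out
}

#' Exact second-order centrality
#'
#' The standard deviation of the first-return time of a perpetual uniform
#' random walk to each node, computed exactly from the chain's
#' first-return-time moments; lower values mark more central nodes.
#' Disconnected inputs are handled per connected component (with a warning);
#' isolated nodes are undefined (NA).
#'
#' @param g an undirected igraph with >= 2 nodes per analysed component.
#' @return named \code{centrality_vector}.
#' @export
second_order_exact <- function(g) {
  n <- igraph::vcount(g)
  nm <- graph_names(g)
  comp <- igraph::components(g)
  if (comp$no > 1)
    warning("graph is disconnected; second-order centrality computed ",
            "per component")
  v <- rep(NA_real_, n)
  for (c in seq_len(comp$no)) {
    members <- which(comp$membership == c)
    if (length(members) < 2) next
    A <- igraph::as_adjacency_matrix(
      igraph::induced_subgraph(g, members), sparse = FALSE)
    v[members] <- second_order_component(A)
  }
  cvec(stats::setNames(v, nm), "second_order", FALSE)
}

#' Monte-Carlo second-order centrality
#'
#' Simulates one long uniform random walk and reports, per node, the sample
#' standard deviation of the gaps between successive visits.  Nodes never
#' revisited within the walk are returned as NA.
#'
#' @param g a connected undirected igraph (walk runs on the component of the
#'   start node).
#' @param n_steps walk length (>= 1e4).
#' @param seed integer seed.
#' @return named \code{centrality_vector}.
#' @export
second_order_mc <- function(g, n_steps = 2e5, seed = 1L) {
  if (n_steps < 1e4) stop("n_steps must be >= 1e4")
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  if (any(lengths(adj) == 0))
    stop("graph has isolated nodes; walk undefined")
  set.seed(as.integer(seed))
  steps <- as.integer(n_steps)
  rnd <- runif(steps)
  path <- integer(steps)
  cur <- 1L
  for (t in seq_len(steps)) {
    nb <- adj[[cur]]
    cur <- nb[1L + as.integer(rnd[t] * length(nb))]
    path[t] <- cur
  }
  times <- split(seq_len(steps), path)
  v <- rep(NA_real_, n)
  for (nm_i in names(times)) {
    gaps <- diff(times[[nm_i]])
    if (length(gaps) >= 2) v[as.integer(nm_i)] <- sd(gaps)
  }
  cvec(stats::setNames(v, graph_names(g)), "second_order", FALSE)
}

measure_fun <- function(measure) {
  switch(measure,
    degree = degree_centrality,
    closeness = closeness_centrality,
    second_order = second_order_exact,
    betweenness = betweenness_centrality,
    stop("unknown measure: ", measure))
}

#' Daily-mean centrality series
#'
#' @param graphs list of igraphs (e.g. from
#'   \code{\link{build_daily_networks}} or snapshots).
#' @param measure one of \code{"degree"}, \code{"closeness"},
#'   \code{"second_order"}, \code{"betweenness"}.
#' @param ... passed to the measure function (e.g. \code{normalized}).
#' @return data.frame (class \code{centrality_series}) with columns
#'   day, mean, n; empty graphs yield NA means (a gap, not a zero).
#' @export
centrality_series <- function(graphs, measure = "degree", ...) {
  if (!length(graphs)) stop("need at least one graph")
  fn <- measure_fun(measure)
  days <- if (!is.null(names(graphs))) as.integer(names(graphs))
  else seq_along(graphs) - 1L
  rows <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    n <- igraph::vcount(g)
    if (n == 0) return(data.frame(day = days[i], mean = NA_real_, n = 0L))
    v <- fn(g, ...)
    data.frame(day = days[i], mean = mean(v, na.rm = TRUE), n = n)
  })
  out <- do.call(rbind, rows)
  attr(out, "measure") <- measure
  class(out) <- c("centrality_series", "data.frame")
  out
}

#' Top-k nodes of a centrality vector
#'
#' Ties are broken by node id (lexicographic), so the selection is
#' deterministic; if the graph has fewer than k nodes all are returned.
#' NA values rank last.
#'
#' @param values a named \code{centrality_vector} (or named numeric).
#' @param k number of nodes (default 100).
#' @return character vector of node ids, highest value first.
#' @export
top_k <- function(values, k = 100L) {
  if (k < 1) stop("k must be >= 1")
  ids <- names(values)
  if (is.null(ids)) stop("values must be named by node id")
  ord <- order(-as.numeric(values), ids, na.last = TRUE)
  ids[ord][seq_len(min(k, length(values)))]
}
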