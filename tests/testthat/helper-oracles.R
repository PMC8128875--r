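# Independent brute-force oracles, deliberately written against plain
# adjacency lists rather than through the package or igraph code paths.

# adjacency list (integer neighbours) from an igraph
oracle_adj <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- rep(list(integer()), n)
  if (nrow(el)) {
    for (r in seq_len(nrow(el))) {
      adj[[el[r, 1]]] <- c(adj[[el[r, 1]]], el[r, 2])
      adj[[el[r, 2]]] <- c(adj[[el[r, 2]]], el[r, 1])
    }
  }
  adj
}

# BFS distances from one source; Inf when unreachable
oracle_bfs <- function(adj, s) {
  n <- length(adj)
  dist <- rep(Inf, n)
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer()
    for (v in frontier) for (w in adj[[v]])
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
    frontier <- unique(nxt)
  }
  dist
}

# closeness: 1 / sum of distances to reachable nodes, 0 for isolates
oracle_closeness <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  vapply(seq_len(n), function(s) {
    d <- oracle_bfs(adj, s)
    d <- d[is.finite(d) & seq_len(n) != s]
    if (!length(d)) 0 else 1 / sum(d)
  }, numeric(1))
}

# betweenness by explicit enumeration of all shortest paths (graphs <= 8
# nodes); normalised by (N-1)(N-2)/2
oracle_betweenness <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  score <- numeric(n)
  all_paths <- function(s, t, dst) {
    # enumerate shortest s->t paths by backward walk on the BFS DAG
    paths <- list()
    grow <- function(path) {
      v <- path[length(path)]
      if (v == t) { paths[[length(paths) + 1L]] <<- path; return() }
      for (w in adj[[v]]) if (dst[w] == dst[v] + 1) grow(c(path, w))
    }
    grow(s)
    paths
  }
  for (s in seq_len(n - 1)) {
    ds <- oracle_bfs(adj, s)
    for (t in (s + 1):n) {
      if (!is.finite(ds[t])) next
      paths <- all_paths(s, t, ds)
      if (!length(paths)) next
      inner <- table(unlist(lapply(paths, function(p) p[-c(1, length(p))])))
      if (length(inner))
        score[as.integer(names(inner))] <-
          score[as.integer(names(inner))] + as.numeric(inner) / length(paths)
    }
  }
  if (n >= 3) score / ((n - 1) * (n - 2) / 2) else score
}

# brute-force TF-IDF: per-document loops, no shared code with the package
oracle_tfidf <- function(docs, top_n = 30L) {
  N <- length(docs)
  grams <- function(tok) {
    out <- tok
    if (length(tok) >= 2)
      out <- c(out, paste(tok[-length(tok)], tok[-1]))
    out
  }
  per_doc <- lapply(docs, grams)
  terms <- sort(unique(unlist(per_doc)))
  score <- numeric(length(terms)); names(score) <- terms
  df <- numeric(length(terms)); names(df) <- terms
  for (tm in terms)
    df[tm] <- sum(vapply(per_doc, function(d) tm %in% d, logical(1)))
  for (d in per_doc) {
    for (tm in unique(d)) {
      tf <- sum(d == tm)
      idf <- log((1 + N) / (1 + df[tm])) + 1
      score[tm] <- score[tm] + tf * idf
    }
  }
  ord <- order(-score, terms)
  data.frame(term = terms[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)[seq_len(min(top_n, length(terms))), ]
}

# random connected graph with <= n_max nodes
oracle_random_connected <- function(n_max = 15, n_min = 4) {
  repeat {
    n <- sample(n_min:n_max, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.6))
    if (igraph::is_connected(g) && igraph::vcount(g) >= 2) return(g)
  }
}
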