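# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (exhaustive enumeration, plain bisection) so that they
# cannot share a defect with the implementation under test.

# all simple paths between two vertices of an igraph, with total weights
brute_force_paths <- function(g, src, sink) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  W <- matrix(Inf, n, n)
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  w <- igraph::E(g)$weight
  for (k in seq_along(w)) {
    W[en[k, 1], en[k, 2]] <- W[en[k, 2], en[k, 1]] <- min(w[k], W[en[k, 1], en[k, 2]])
  }
  s <- if (is.character(src)) match(src, nm) else src
  t <- if (is.character(sink)) match(sink, nm) else sink
  paths <- list(); weights <- numeric(0)
  visit <- function(path, wsum) {
    cur <- path[length(path)]
    if (cur == t) {
      paths[[length(paths) + 1]] <<- path
      weights <<- c(weights, wsum)
      return()
    }
    for (u in adj[[cur]]) {
      if (!(u %in% path)) visit(c(path, u), wsum + W[cur, u])
    }
  }
  visit(s, 0)
  list(paths = lapply(paths, function(p) nm[p]), weights = weights)
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(rgs, mx) {
    k <- length(rgs)
    if (k == n) {
      out[[length(out) + 1]] <<- rgs
      return()
    }
    for (v in seq_len(mx + 1)) grow(c(rgs, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# random connected weighted residue-graph-like igraph
random_test_graph <- function(n, seed, p = 0.45) {
  set.seed(seed)
  repeat {
    adj <- matrix(stats::runif(n * n) < p, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj + t(adj), mode = "undirected")
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  absc <- stats::runif(igraph::ecount(g), 0.1, 0.99)
  igraph::E(g)$abs_c <- absc
  igraph::E(g)$weight <- -log(absc)
  g
}

# adjusted Rand index between two labellings
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# brute-force maximum weighted modularity over every partition of the
# vertex set, computed straight from the definition
# Q = sum_c [ e_c/m - (d_c/(2m))^2 ]
brute_force_modularity_max <- function(g, weights) {
  n <- igraph::vcount(g)
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  m <- sum(weights)
  deg <- numeric(n)
  for (k in seq_along(weights)) {
    deg[en[k, 1]] <- deg[en[k, 1]] + weights[k]
    deg[en[k, 2]] <- deg[en[k, 2]] + weights[k]
  }
  best <- -Inf
  for (p in all_partitions(n)) {
    q <- 0
    for (cm in unique(p)) {
      inside <- sum(weights[p[en[, 1]] == cm & p[en[, 2]] == cm])
      q <- q + inside / m - (sum(deg[p == cm]) / (2 * m))^2
    }
    if (q > best) best <- q
  }
  best
}

# canonical two-community test graph: two complete blocks (sizes 3-4),
# one weak bridge, random correlation strengths
random_two_community_graph <- function(seed) {
  set.seed(seed)
  n1 <- sample(3:4, 1); n2 <- sample(3:4, 1); n <- n1 + n2
  adj <- matrix(0, n, n)
  adj[1:n1, 1:n1] <- 1
  adj[(n1 + 1):n, (n1 + 1):n] <- 1
  diag(adj) <- 0
  i <- sample(1:n1, 1); j <- sample((n1 + 1):n, 1)
  adj[i, j] <- adj[j, i] <- 1
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  intra <- (en[, 1] <= n1) == (en[, 2] <= n1)
  absc <- ifelse(intra, stats::runif(igraph::ecount(g), 0.5, 0.95),
                 stats::runif(1, 0.05, 0.3))
  igraph::E(g)$abs_c <- absc
  igraph::E(g)$weight <- -log(absc)
  list(g = g, truth = rep(1:2, c(n1, n2)))
}

# canonical form of an undirected simple path (smaller end first)
path_key <- function(p) {
  if (p[1] > p[length(p)]) p <- rev(p)
  paste(p, collapse = ">")
}
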