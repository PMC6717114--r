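#' Build a correlation-weighted residue contact network
#'
#' Nodes are residues (named `chain:resno`); an edge joins residues i and
#' j iff their contact occupancy reaches `occ_min` (the 4.5 A / 75%
#' criterion, or its Calpha fallback) and they are not sequence
#' neighbours within a chain (|i-j| > 1; cross-chain pairs are always
#' eligible). Edge weights are `w_ij = -log(|c_ij|)` (natural log), the
#' information-transfer cost; edges with `|c_ij| < c_floor` are dropped
#' as numerically meaningless.
#'
#' @param occupancy symmetric occupancy matrix from [contact_occupancy].
#' @param corr symmetric correlation matrix from [correlation_matrix].
#' @param topology data.frame with `node`, `chain`, `resno` (row order
#'   matching the matrices).
#' @param occ_min minimum occupancy for an edge (default 0.75).
#' @param c_floor minimum |correlation| for an edge (default 1e-4).
#' @param coords optional reference coordinates (n x 3) stored on nodes.
#' @return object of class `residue_graph`: an igraph with vertex
#'   attributes `chain`, `resno` (and `x`,`y`,`z` when `coords` given)
#'   and edge attributes `weight` (= w), `abs_c`, `occupancy`.
#' @export
build_network <- function(occupancy, corr, topology, occ_min = 0.75,
                          c_floor = 1e-4, coords = NULL) {
  n <- nrow(occupancy)
  stopifnot(ncol(occupancy) == n, all(dim(corr) == c(n, n)),
            nrow(topology) == n)
  name <- paste0(topology$chain, ":", topology$resno)
  eligible <- matrix(TRUE, n, n)
  same_chain <- outer(topology$chain, topology$chain, "==")
  near_seq <- abs(outer(topology$resno, topology$resno, "-")) <= 1
  eligible[same_chain & near_seq] <- FALSE
  diag(eligible) <- FALSE
  keep <- eligible & occupancy >= occ_min &
    !is.na(corr) & abs(corr) >= c_floor
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = name)
  g <- igraph::set_vertex_attr(g, "chain", value = topology$chain)
  g <- igraph::set_vertex_attr(g, "resno", value = topology$resno)
  if (!is.null(coords)) {
    g <- igraph::set_vertex_attr(g, "x", value = coords[, 1])
    g <- igraph::set_vertex_attr(g, "y", value = coords[, 2])
    g <- igraph::set_vertex_attr(g, "z", value = coords[, 3])
  }
  if (nrow(idx) > 0) {
    ac <- abs(corr[idx])
    g <- igraph::add_edges(g, as.vector(t(idx)))
    g <- igraph::set_edge_attr(g, "abs_c", value = ac)
    g <- igraph::set_edge_attr(g, "weight", value = -log(ac))
    g <- igraph::set_edge_attr(g, "occupancy", value = occupancy[idx])
  } else {
    warning("build_network: empty graph (no residue pair met the criteria)")
  }
  class(g) <- c("residue_graph", class(g))
  g
}

#' Residue network straight from a trajectory
#'
#' Convenience wrapper: superpose, trim flexible chain termini, compute
#' contact occupancy and dynamical cross-correlation, and build the
#' weighted graph.
#'
#' @param ens a [trajectory_ensemble].
#' @param occ_min,c_floor passed to [build_network].
#' @param cutoff,ca_cutoff passed to [contact_occupancy].
#' @param trim_termini residues dropped from each chain terminus before
#'   network construction (flexible ends; default 3).
#' @return a `residue_graph` (see [build_network]).
#' @export
residue_network <- function(ens, occ_min = 0.75, c_floor = 1e-4,
                            cutoff = 4.5, ca_cutoff = 8.5,
                            trim_termini = 3) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (!isTRUE(ens$aligned)) ens <- superpose(ens)
  keep <- unlist(lapply(split(seq_len(nrow(ens$topology)),
                              ens$topology$chain), function(ix) {
    if (trim_termini > 0 && length(ix) > 2 * trim_termini) {
      ix[(trim_termini + 1):(length(ix) - trim_termini)]
    } else ix
  }), use.names = FALSE)
  keep <- sort(keep)
  sub <- trajectory_ensemble(ens$coords[, keep, , drop = FALSE],
                             ens$topology[keep, , drop = FALSE],
                             ens$units, ens$truth)
  sub$aligned <- TRUE
  occ <- contact_occupancy(sub, cutoff = cutoff, ca_cutoff = ca_cutoff)
  cc <- correlation_matrix(sub)
  build_network(occ, cc, sub$topology, occ_min = occ_min,
                c_floor = c_floor,
                coords = apply(sub$coords, c(2, 3), mean))
}

# deterministic edge ordering key for tie-breaks: sorted endpoint names
.edge_keys <- function(g) {
  en <- igraph::ends(g, igraph::E(g), names = TRUE)
  apply(en, 1, function(r) paste(sort(r), collapse = "|"))
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge of highest weighted betweenness (edge
#' weights `w = -log|c|` acting as lengths), tracking the component
#' partition after every removal, and returns the partition that
#' maximises weighted modularity, with `|c|` (edge attribute `abs_c`) as
#' connection strength. Ties in betweenness are broken lexicographically
#' by edge endpoints for determinism.
#'
#' @param g a `residue_graph` (or igraph with `weight` and `abs_c` edge
#'   attributes).
#' @return object of class `community_partition`: list with `membership`
#'   (named integer vector), `modularity`, `n_communities`.
#' @export
communities_gn <- function(g) {
  stopifnot(igraph::is_igraph(g))
  n <- igraph::vcount(g)
  if (n == 1 || igraph::ecount(g) == 0) {
    memb <- seq_len(n)
    names(memb) <- igraph::V(g)$name
    return(structure(list(membership = memb,
                          modularity = if (igraph::ecount(g) == 0) NA_real_
                                       else 0,
                          n_communities = n),
                     class = "community_partition"))
  }
  strength <- igraph::E(g)$abs_c
  if (is.null(strength)) strength <- rep(1, igraph::ecount(g))
  full <- g
  igraph::E(full)$strength <- strength
  work <- full
  best <- list(modularity = -Inf, membership = NULL)
  eval_partition <- function(memb) {
    q <- igraph::modularity(full, memb, weights = igraph::E(full)$strength)
    if (q > best$modularity) best <<- list(modularity = q, membership = memb)
  }
  eval_partition(igraph::components(work)$membership)
  while (igraph::ecount(work) > 0) {
    eb <- igraph::edge_betweenness(work, weights = igraph::E(work)$weight)
    top <- which(eb == max(eb))
    if (length(top) > 1) {
      # ties are common (betweenness counts path pairs): cut the weakest
      # correlation first, then break residual ties lexicographically
      wtop <- igraph::E(work)$weight[top]
      top <- top[wtop == max(wtop)]
      if (length(top) > 1) top <- top[order(.edge_keys(work)[top])][1]
    }
    work <- igraph::delete_edges(work, top)
    eval_partition(igraph::components(work)$membership)
  }
  memb <- best$membership
  names(memb) <- igraph::V(full)$name
  structure(list(membership = memb, modularity = best$modularity,
                 n_communities = length(unique(memb))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d communities, modularity %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

# All-pairs shortest path distances by Floyd-Warshall on the weight
# matrix. Returns the distance matrix (Inf where disconnected).
.floyd_warshall <- function(g) {
  n <- igraph::vcount(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  w <- igraph::E(g)$weight
  for (k in seq_along(w)) {
    i <- en[k, 1]; j <- en[k, 2]
    if (w[k] < D[i, j]) D[i, j] <- D[j, i] <- w[k]
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    upd <- Dk < D
    D[upd] <- Dk[upd]
  }
  D
}

# resolve a vertex argument (name or index) to an index
.vid <- function(g, v) {
  if (is.character(v)) {
    ix <- match(v, igraph::V(g)$name)
    if (is.na(ix)) stop("unknown vertex: ", v)
    ix
  } else as.integer(v)
}

#' Optimal (minimum-weight) path between two residues
#'
#' All-pairs shortest-path distances are computed with Floyd-Warshall on
#' the `-log|c|` weights; the path itself is reconstructed greedily from
#' the distance table (each step moves to the neighbour that preserves
#' the remaining shortest distance), with ties broken lexicographically
#' by node name for determinism.
#'
#' @param g a `residue_graph`.
#' @param src,sink vertex names (`"chain:resno"`) or indices.
#' @return list with `path` (vertex names), `weight` (total), `n_edges`;
#'   or an object with `weight = Inf` and empty path when disconnected
#'   (no-path signal).
#' @export
optimal_path <- function(g, src, sink) {
  s <- .vid(g, src); t <- .vid(g, sink)
  nm <- igraph::V(g)$name
  if (s == t) return(list(path = nm[s], weight = 0, n_edges = 0L))
  D <- .floyd_warshall(g)
  if (!is.finite(D[s, t])) {
    return(list(path = character(0), weight = Inf, n_edges = NA_integer_))
  }
  adj <- igraph::as_adj_list(g, mode = "all")
  path <- s
  cur <- s
  visited <- rep(FALSE, igraph::vcount(g))
  visited[s] <- TRUE
  while (cur != t) {
    nbr <- as.integer(adj[[cur]])
    nbr <- nbr[!visited[nbr] | nbr == t]
    ew <- vapply(nbr, function(u) {
      eid <- igraph::get_edge_ids(g, c(cur, u))
      igraph::E(g)$weight[eid]
    }, numeric(1))
    tot <- ew + D[nbr, t]
    on_sp <- which(abs(tot - D[cur, t]) < 1e-10)
    if (length(on_sp) == 0) on_sp <- which.min(tot)   # numerical guard
    pick <- on_sp[order(nm[nbr[on_sp]])][1]
    cur <- nbr[pick]
    visited[cur] <- TRUE
    path <- c(path, cur)
  }
  list(path = nm[path], weight = D[s, t], n_edges = length(path) - 1L)
}

#' Suboptimal force-propagation paths
#'
#' Enumerates simple paths from `src` to `sink` whose edge count does not
#' exceed the optimal path's edge count plus `edge_slack` (default 20,
#' the "up to 20 edges longer" criterion). An alternative weight-based
#' criterion (`weight_slack`: total weight within `optimal + slack`) can
#' be used instead. Paths are ranked by total weight. Enumeration is
#' depth-first with hop- and weight-based pruning and stops at
#' `max_paths`, flagging truncation.
#'
#' @param g a `residue_graph`.
#' @param src,sink vertex names or indices.
#' @param edge_slack extra edges allowed over the optimal edge count.
#' @param weight_slack if non-NULL, use total weight <= optimal +
#'   `weight_slack` as the criterion instead of edge count.
#' @param max_paths cap on the number of collected paths (default 1000).
#' @return object of class `path_set`: list with `src`, `sink`,
#'   `optimal` (from [optimal_path]), `paths` (list of vertex-name
#'   vectors, ranked by weight), `weights`, `n_edges`, `criterion`,
#'   `truncated`.
#' @export
suboptimal_paths <- function(g, src, sink, edge_slack = 20,
                             weight_slack = NULL, max_paths = 1000) {
  s <- .vid(g, src); t <- .vid(g, sink)
  nm <- igraph::V(g)$name
  opt <- optimal_path(g, s, t)
  if (!is.finite(opt$weight)) stop("suboptimal_paths: src and sink disconnected")
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(v) as.integer(v)[order(nm[as.integer(v)])])
  W <- matrix(Inf, n, n)
  en <- igraph::ends(g, igraph::E(g), names = FALSE)
  ew <- igraph::E(g)$weight
  for (k in seq_along(ew)) {
    W[en[k, 1], en[k, 2]] <- W[en[k, 2], en[k, 1]] <-
      min(ew[k], W[en[k, 1], en[k, 2]])
  }
  # pruning tables: min hops and min weight from every node to the sink
  hops <- rep(Inf, n); hops[t] <- 0
  frontier <- t
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (u in adj[[v]]) if (hops[u] > hops[v] + 1) {
        hops[u] <- hops[v] + 1
        nxt <- c(nxt, u)
      }
    }
    frontier <- unique(nxt)
  }
  D <- .floyd_warshall(g)
  use_weight <- !is.null(weight_slack)
  max_edges <- if (use_weight) Inf else opt$n_edges + edge_slack
  max_w <- if (use_weight) opt$weight + weight_slack else Inf
  paths <- list(); weights <- numeric(0)
  truncated <- FALSE
  stack_path <- integer(n + 1)
  on_path <- rep(FALSE, n)
  recurse <- function(cur, depth, wsum) {
    if (truncated) return()
    if (cur == t) {
      paths[[length(paths) + 1]] <<- stack_path[1:depth]
      weights <<- c(weights, wsum)
      if (length(paths) >= max_paths) truncated <<- TRUE
      return()
    }
    for (u in adj[[cur]]) {
      if (on_path[u]) next
      wnew <- wsum + W[cur, u]
      if (depth + hops[u] > max_edges) next
      if (wnew + D[u, t] > max_w + 1e-12) next
      on_path[u] <<- TRUE
      stack_path[depth + 1] <<- u
      recurse(u, depth + 1L, wnew)
      on_path[u] <<- FALSE
      if (truncated) return()
    }
  }
  on_path[s] <- TRUE
  stack_path[1] <- s
  recurse(s, 1L, 0)
  ord <- order(weights, vapply(paths, function(p)
    paste(nm[p], collapse = "|"), character(1)))
  paths <- paths[ord]; weights <- weights[ord]
  structure(list(src = nm[s], sink = nm[t], optimal = opt,
                 paths = lapply(paths, function(p) nm[p]),
                 weights = weights,
                 n_edges = vapply(paths, length, integer(1)) - 1L,
                 criterion = if (use_weight) "weight" else "edges",
                 slack = if (use_weight) weight_slack else edge_slack,
                 truncated = truncated),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("Path set %s -> %s: optimal weight %.4f (%d edges), %d paths (%s slack %g)%s\n",
              x$src, x$sink, x$optimal$weight, x$optimal$n_edges,
              length(x$paths), x$criterion, x$slack,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Edge and node usage across a path set
#'
#' Fraction of paths in the set that traverse each edge (and each node):
#' the concentration of force propagation. High-usage edges are the
#' critical links whose loss would reroute or break propagation.
#'
#' @param ps a `path_set` from [suboptimal_paths].
#' @return list with `edges` (data.frame `from`, `to`, `usage`, sorted
#'   decreasing) and `nodes` (data.frame `node`, `usage`).
#' @export
edge_usage <- function(ps) {
  stopifnot(inherits(ps, "path_set"))
  np <- length(ps$paths)
  if (np == 0) stop("edge_usage: empty path set")
  etab <- new.env(parent = emptyenv())
  ntab <- new.env(parent = emptyenv())
  for (p in ps$paths) {
    for (v in unique(p)) {
      ntab[[v]] <- (if (is.null(ntab[[v]])) 0 else ntab[[v]]) + 1
    }
    if (length(p) > 1) {
      for (k in seq_len(length(p) - 1)) {
        key <- paste(sort(c(p[k], p[k + 1])), collapse = "|")
        etab[[key]] <- (if (is.null(etab[[key]])) 0 else etab[[key]]) + 1
      }
    }
  }
  ekeys <- ls(etab)
  eparts <- strsplit(ekeys, "|", fixed = TRUE)
  edges <- data.frame(
    from = vapply(eparts, `[`, character(1), 1),
    to = vapply(eparts, `[`, character(1), 2),
    usage = vapply(ekeys, function(k) etab[[k]], numeric(1)) / np,
    stringsAsFactors = FALSE)
  edges <- edges[order(-edges$usage, edges$from, edges$to), ]
  rownames(edges) <- NULL
  nkeys <- ls(ntab)
  nodes <- data.frame(
    node = nkeys,
    usage = vapply(nkeys, function(k) ntab[[k]], numeric(1)) / np,
    stringsAsFactors = FALSE)
  nodes <- nodes[order(-nodes$usage, nodes$node), ]
  rownames(nodes) <- NULL
  list(edges = edges, nodes = nodes)
}

#' Orthogonal component of a path relative to the pulling axis
#'
#' Decomposes each step between consecutive path nodes into components
#' parallel and perpendicular to the pulling axis. Returns the overall
#' orthogonal fraction `sum(|d_perp|)/sum(|d|)`, the largest single-step
#' orthogonal fraction, and that step's normalised position along the
#' path (0 = source end, 1 = sink end). A step perpendicular to the axis
#' scores 1; a collinear step scores 0.
#'
#' @param path_coords matrix (n_nodes x 3) of node coordinates along the
#'   path, in path order.
#' @param pulling_axis length-3 vector (need not be normalised).
#' @return list with `orthogonal_fraction`, `max_step_fraction`,
#'   `max_step_position`, `step_fractions`.
#' @export
orthogonal_index <- function(path_coords, pulling_axis) {
  stopifnot(is.matrix(path_coords), ncol(path_coords) == 3,
            length(pulling_axis) == 3)
  if (nrow(path_coords) < 2) stop("orthogonal_index: path has no steps")
  u <- pulling_axis / sqrt(sum(pulling_axis^2))
  if (!all(is.finite(u))) stop("orthogonal_index: zero pulling axis")
  d <- diff(path_coords)
  par <- d %*% u
  perp <- d - outer(as.vector(par), u)
  len <- sqrt(rowSums(d^2))
  plen <- sqrt(rowSums(perp^2))
  if (sum(len) == 0) stop("orthogonal_index: zero-length path")
  frac <- ifelse(len > 0, plen / len, 0)
  k <- which.max(frac)
  ns <- nrow(d)
  list(orthogonal_fraction = sum(plen) / sum(len),
       max_step_fraction = frac[k],
       max_step_position = if (ns == 1) 0.5 else (k - 0.5) / ns,
       step_fractions = frac)
}
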