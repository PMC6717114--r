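test_that("contact occupancy counts frames below the cutoff", {
  # two residues exactly 4.0 A apart in every frame -> occupancy 1;
  # 9.0 A -> 0; below cutoff in exactly 600/800 frames -> 0.75
  nf <- 800
  coords <- array(0, c(nf, 3, 3))
  coords[, 2, 1] <- 4.0
  coords[, 3, 1] <- ifelse(seq_len(nf) <= 600, 8.0, 9.0)
  topo <- data.frame(node = 1:3, chain = "A", resno = c(1, 5, 9))
  ens <- trajectory_ensemble(coords, topo, "angstrom")
  ens$aligned <- TRUE
  occ <- contact_occupancy(ens)
  expect_equal(occ[1, 2], 1)
  expect_equal(occ[1, 3], 0.75)
  expect_identical(attr(occ, "mode"), "calpha_fallback")
})

test_that("correlation matrix fixes the unit diagonal and identical
           motion", {
  set.seed(6)
  nf <- 200
  coords <- array(rnorm(nf * 4 * 3, sd = 0.5), c(nf, 4, 3))
  coords[, 2, ] <- coords[, 1, ]          # residue 2 moves with residue 1
  topo <- data.frame(node = 1:4, chain = "A", resno = 1:4)
  ens <- trajectory_ensemble(coords, topo, "angstrom")
  ens$aligned <- TRUE
  C <- correlation_matrix(ens)
  expect_equal(diag(C), rep(1, 4))
  expect_equal(C[1, 2], 1, tolerance = 1e-12)
  expect_true(isSymmetric(C))
})

test_that("network construction matches a hand-enumerated toy system", {
  # 6 residues, two chains; occupancy and correlation set by hand
  topo <- data.frame(node = 1:6, chain = rep(c("A", "B"), each = 3),
                     resno = c(1, 2, 3, 1, 2, 3))
  occ <- matrix(0, 6, 6)
  occ[1, 3] <- occ[3, 1] <- 0.9    # A1-A3: |i-j|=2, eligible
  occ[1, 2] <- occ[2, 1] <- 0.9    # A1-A2: sequence neighbours, dropped
  occ[1, 4] <- occ[4, 1] <- 0.8    # A1-B1: cross-chain, eligible
  occ[2, 5] <- occ[5, 2] <- 0.5    # below occupancy threshold
  occ[3, 6] <- occ[6, 3] <- 1.0    # A3-B3 eligible
  occ[4, 6] <- occ[6, 4] <- 0.9    # B1-B3 eligible but |c| below floor
  diag(occ) <- 1
  corr <- matrix(0.5, 6, 6); diag(corr) <- 1
  corr[4, 6] <- corr[6, 4] <- 1e-6
  corr[3, 6] <- corr[6, 3] <- 0.1
  g <- build_network(occ, corr, topo)
  en <- igraph::ends(g, igraph::E(g))
  keys <- sort(apply(en, 1, function(r) paste(sort(r), collapse = "-")))
  expect_identical(keys, sort(c("A:1-A:3", "A:1-B:1", "A:3-B:3")))
  # natural-log weights and exact symmetry
  eid <- igraph::get_edge_ids(g, c("A:3", "B:3"))
  expect_equal(igraph::E(g)$weight[eid], -log(0.1), tolerance = 1e-12)
  expect_equal(igraph::E(g)$weight[igraph::get_edge_ids(g, c("B:3", "A:3"))],
               igraph::E(g)$weight[eid])
})

test_that("weights order inversely with correlation strength", {
  topo <- data.frame(node = 1:4, chain = "A", resno = c(1, 3, 5, 7))
  occ <- matrix(1, 4, 4)
  corr <- diag(4)
  cs <- c(0.2, 0.5, 0.9)
  corr[1, 2] <- corr[2, 1] <- cs[1]
  corr[2, 3] <- corr[3, 2] <- cs[2]
  corr[3, 4] <- corr[4, 3] <- cs[3]
  g <- build_network(occ, corr, topo)
  w <- vapply(list(c("A:1", "A:3"), c("A:3", "A:5"), c("A:5", "A:7")),
              function(pr) igraph::E(g)$weight[igraph::get_edge_ids(g, pr)],
              numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("Girvan-Newman splits the canonical two-clique graph and
           attains the brute-force maximum modularity on a small graph", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1
  adj[5, 6] <- adj[6, 5] <- 1
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", 1:10)
  igraph::E(g)$weight <- 1
  igraph::E(g)$abs_c <- exp(-1)
  part <- communities_gn(g)
  expect_equal(ari(part$membership, rep(1:2, each = 5)), 1)
  # exhaustive-partition oracle on an 8-node graph
  adj8 <- matrix(0, 8, 8)
  adj8[1:4, 1:4] <- 1; adj8[5:8, 5:8] <- 1
  adj8[4, 5] <- adj8[5, 4] <- 1
  diag(adj8) <- 0
  g8 <- igraph::graph_from_adjacency_matrix(adj8, mode = "undirected")
  igraph::V(g8)$name <- sprintf("n%d", 1:8)
  set.seed(8)
  igraph::E(g8)$abs_c <- runif(igraph::ecount(g8), 0.5, 0.9)
  igraph::E(g8)$weight <- -log(igraph::E(g8)$abs_c)
  best_q <- max(vapply(all_partitions(8), function(m) {
    igraph::modularity(g8, m, weights = igraph::E(g8)$abs_c)
  }, numeric(1)))
  p8 <- communities_gn(g8)
  expect_equal(p8$modularity, best_q, tolerance = 1e-12)
})

test_that("optimal path prefers strong-correlation detours and matches
           brute force on random graphs", {
  # direct edge w=1 vs two-hop 0.4+0.4
  topo <- data.frame(node = 1:3, chain = "A", resno = c(1, 3, 5))
  occ <- matrix(1, 3, 3)
  corr <- diag(3)
  corr[1, 3] <- corr[3, 1] <- exp(-1)
  corr[1, 2] <- corr[2, 1] <- exp(-0.4)
  corr[2, 3] <- corr[3, 2] <- exp(-0.4)
  g <- build_network(occ, corr, topo)
  op <- optimal_path(g, "A:1", "A:5")
  expect_identical(op$path, c("A:1", "A:3", "A:5"))
  expect_equal(op$weight, 0.8, tolerance = 1e-12)
  # src = sink
  expect_equal(optimal_path(g, "A:1", "A:1")$weight, 0)
  # brute-force equivalence on 20 random graphs
  for (s in 1:20) {
    gr <- random_test_graph(sample(5:8, 1), seed = 400 + s)
    vs <- sample(igraph::vcount(gr), 2)
    op <- optimal_path(gr, vs[1], vs[2])
    bf <- brute_force_paths(gr, vs[1], vs[2])
    expect_equal(op$weight, min(bf$weights), tolerance = 1e-12)
    expect_identical(path_key(op$path),
                     path_key(bf$paths[[which.min(bf$weights)]]))
  }
})

test_that("suboptimal path enumeration equals exhaustive enumeration and
           grows with slack", {
  gr <- random_test_graph(8, seed = 77)
  bf <- brute_force_paths(gr, 1, 8)
  opt_edges <- length(bf$paths[[which.min(bf$weights)]]) - 1
  ps <- suboptimal_paths(gr, 1, 8, edge_slack = 2, max_paths = 1e6)
  keep <- vapply(bf$paths, length, integer(1)) - 1 <= opt_edges + 2
  expect_setequal(vapply(ps$paths, path_key, character(1)),
                  vapply(bf$paths[keep], path_key, character(1)))
  expect_equal(sort(ps$weights), sort(bf$weights[keep]), tolerance = 1e-12)
  # slack 0 with a unique shortest path returns exactly that path
  ps0 <- suboptimal_paths(gr, 1, 8, edge_slack = 0, max_paths = 1e6)
  expect_true(path_key(ps0$paths[[1]]) %in%
                vapply(bf$paths[vapply(bf$paths, length, integer(1)) - 1 ==
                                  opt_edges], path_key, character(1)))
  # path count is non-decreasing in slack
  counts <- vapply(0:3, function(sl) {
    length(suboptimal_paths(gr, 1, 8, edge_slack = sl,
                            max_paths = 1e6)$paths)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("edge usage reports traversal fractions", {
  gr <- random_test_graph(7, seed = 99)
  ps <- suboptimal_paths(gr, 1, 7, edge_slack = 1, max_paths = 1e6)
  u <- edge_usage(ps)
  expect_true(all(u$edges$usage > 0 & u$edges$usage <= 1))
  # a single path gives usage 1 on each of its edges
  ps1 <- suboptimal_paths(gr, 1, 7, edge_slack = 0, max_paths = 1e6)
  if (length(ps1$paths) == 1) {
    expect_true(all(edge_usage(ps1)$edges$usage == 1))
  }
  # source and sink are on every path
  expect_equal(u$nodes$usage[u$nodes$node == ps$src], 1)
  expect_equal(u$nodes$usage[u$nodes$node == ps$sink], 1)
})

test_that("orthogonal index decomposes hand geometries", {
  axis <- c(1, 0, 0)
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(orthogonal_index(collinear, axis)$orthogonal_fraction, 0)
  perp <- rbind(c(0, 0, 0), c(0, 1, 0))
  o <- orthogonal_index(perp, axis)
  expect_equal(o$orthogonal_fraction, 1)
  expect_equal(o$max_step_fraction, 1)
  # L-shaped: one axis step plus one equal perpendicular step
  ell <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  o2 <- orthogonal_index(ell, axis)
  expect_equal(o2$orthogonal_fraction, 0.5)
  expect_equal(o2$max_step_position, 0.75)
  expect_error(orthogonal_index(rbind(c(0, 0, 0), c(0, 0, 0)), axis),
               "zero-length")
})

test_that("superposition removes rigid-body motion exactly and RMSF
           matches the Gaussian closure", {
  set.seed(12)
  base <- matrix(rnorm(30), 10, 3)
  nf <- 25
  coords <- array(0, c(nf, 10, 3))
  for (f in 1:nf) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    coords[f, , ] <- base %*% R + matrix(runif(3, -5, 5), 10, 3,
                                         byrow = TRUE)
  }
  topo <- data.frame(node = 1:10, chain = "A", resno = 1:10)
  ens <- superpose(trajectory_ensemble(coords, topo, "angstrom"))
  expect_lt(max(abs(sweep(ens$coords, c(2, 3), ens$mean_structure))), 1e-8)
  expect_lt(max(rmsf(ens)$rmsf), 1e-8)
  # isotropic Gaussian displacements: RMSF ~ sigma*sqrt(3)
  sig <- 0.8
  coords2 <- array(rnorm(5000 * 8 * 3, sd = sig), c(5000, 8, 3))
  coords2 <- sweep(coords2, c(2, 3), matrix(rnorm(24, sd = 20), 8, 3), "+")
  ens2 <- trajectory_ensemble(coords2,
                              data.frame(node = 1:8, chain = "A",
                                         resno = 1:8), "angstrom")
  ens2$aligned <- TRUE
  expect_equal(mean(rmsf(ens2)$rmsf), sig * sqrt(3), tolerance = 0.02)
  # planted high-flexibility block is elevated only there
  coords3 <- array(rnorm(800 * 9 * 3, sd = 0.3), c(800, 9, 3))
  coords3[, 4:6, ] <- coords3[, 4:6, ] * 5
  ens3 <- trajectory_ensemble(coords3,
                              data.frame(node = 1:9, chain = "A",
                                         resno = 1:9), "angstrom")
  ens3$aligned <- TRUE
  r3 <- rmsf(ens3)$rmsf
  expect_true(all(r3[4:6] > 3 * max(r3[c(1:3, 7:9)])))
})

test_that("interdomain angles recover planted rod geometries", {
  rod <- function(theta_deg, n = 8, noise = 0.05, nf = 300, seed = 1) {
    set.seed(seed)
    th <- theta_deg * pi / 180
    # domain A along -x from the joint; domain B at the planted angle
    A <- cbind(-seq_len(n), 0, 0) * 3
    B <- cbind(seq_len(n) * cos(pi - th), seq_len(n) * sin(pi - th), 0) * 3
    coords <- array(0, c(nf, 2 * n, 3))
    for (f in seq_len(nf)) {
      coords[f, , ] <- rbind(A, B) + rnorm(2 * n * 3, sd = noise)
    }
    topo <- data.frame(node = 1:(2 * n), chain = rep(c("A", "B"), each = n),
                       resno = c(1:n, 1:n))
    ens <- trajectory_ensemble(coords, topo, "angstrom")
    ens$aligned <- TRUE
    ens
  }
  straight <- interdomain_angle(rod(180), 1:8, 9:16)
  expect_equal(straight$peak, 180, tolerance = 2 / 180)
  perp <- interdomain_angle(rod(90), 1:8, 9:16)
  expect_equal(perp$peak, 90, tolerance = 2 / 90)
  bent <- interdomain_angle(rod(134, noise = 0.3, seed = 9), 1:8, 9:16)
  expect_equal(bent$peak, 134, tolerance = 2 / 134)
})

test_that("trajectory-to-network pipeline is deterministic and recovers
           planted communities", {
  geo <- make_two_domain_reference(10)
  cfg <- traj_gen_config(
    n_residues_per_chain = 10, n_frames = 1200,
    community_blocks = list(list(nodes = 1:10, rho = 0.7),
                            list(nodes = 11:20, rho = 0.7)),
    background_correlation = 0.05, contact_geometry = geo, seed = 31)
  ens <- gen_trajectory(cfg)
  g1 <- residue_network(ens, trim_termini = 0)
  g2 <- residue_network(ens, trim_termini = 0)
  expect_identical(igraph::as_data_frame(g1), igraph::as_data_frame(g2))
  part <- communities_gn(g1)
  expect_equal(ari(part$membership, rep(1:2, each = 10)), 1)
  ps1 <- suboptimal_paths(g1, "A:1", "B:1", edge_slack = 2)
  ps2 <- suboptimal_paths(g2, "A:1", "B:1", edge_slack = 2)
  expect_identical(ps1$paths, ps2$paths)
})
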