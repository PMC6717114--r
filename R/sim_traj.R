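#' Two-chain reference geometry for synthetic trajectories
#'
#' Lays out two parallel zigzag chains of alpha-carbons (an extended-strand
#' caricature: consecutive Calpha 3.8 A apart, alternating transverse
#' displacement so that second and third sequence neighbours are also
#' within a Calpha contact distance, as in real backbone geometry) with an
#' inter-chain separation putting facing residues of the two chains in
#' contact. Serves as the default `contact_geometry` of [traj_gen_config].
#'
#' @param n_per_chain residues per chain.
#' @param along along-chain advance per residue in A.
#' @param amplitude transverse zigzag amplitude in A (with `along`,
#'   consecutive Calpha are `sqrt(along^2 + amplitude^2)` apart).
#' @param separation inter-chain separation in A.
#' @return list with `coords` (matrix n_nodes x 3, A) and `topology`
#'   (data.frame with `node`, `chain`, `resno`).
#' @export
make_two_chain_reference <- function(n_per_chain, along = 2.6,
                                     amplitude = 2.77, separation = 4.5) {
  n <- 2 * n_per_chain
  i <- seq_len(n_per_chain)
  zig <- amplitude * (i %% 2)
  coords <- matrix(0, n, 3)
  coords[1:n_per_chain, 1] <- along * i
  coords[1:n_per_chain, 2] <- zig
  coords[(n_per_chain + 1):n, 1] <- along * i
  coords[(n_per_chain + 1):n, 2] <- zig + separation
  topology <- data.frame(
    node = seq_len(n),
    chain = rep(c("A", "B"), each = n_per_chain),
    resno = c(i, i))
  list(coords = coords, topology = topology)
}

#' Two compact-domain reference geometry
#'
#' Places each chain's alpha-carbons on a compact 3D grid (a folded-domain
#' caricature: every residue has several spatial neighbours within contact
#' distance, unlike an extended strand) with the two domains facing each
#' other across a narrow interface, so that only the facing grid layers
#' are in cross-chain contact. Suited to community-detection closures,
#' where the planted blocks must be spatially dense modules.
#'
#' @param n_per_chain residues per chain.
#' @param spacing grid spacing in A.
#' @param gap interface gap between the facing layers in A.
#' @return list with `coords` and `topology`, as
#'   [make_two_chain_reference].
#' @export
make_two_domain_reference <- function(n_per_chain, spacing = 5,
                                      gap = 5.5) {
  nx <- ceiling(n_per_chain^(1 / 3))
  ny <- ceiling(sqrt(n_per_chain / nx))
  nz <- ceiling(n_per_chain / (nx * ny))
  grid <- expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz))
  grid <- as.matrix(grid[seq_len(n_per_chain), ]) * spacing
  offset <- max(grid[, 1]) + gap
  coordsB <- grid
  coordsB[, 1] <- offset + (max(grid[, 1]) - grid[, 1])  # mirrored
  coords <- rbind(grid, coordsB)
  dimnames(coords) <- NULL
  topology <- data.frame(
    node = seq_len(2 * n_per_chain),
    chain = rep(c("A", "B"), each = n_per_chain),
    resno = c(seq_len(n_per_chain), seq_len(n_per_chain)))
  list(coords = coords, topology = topology)
}

#' Nearest positive semi-definite repair of a symmetric matrix
#'
#' Clips negative eigenvalues to zero and renormalises the diagonal to 1
#' (correlation form). Standard surrogate for planted correlation targets
#' that are not exactly PSD.
#'
#' @param C symmetric matrix.
#' @return repaired correlation matrix.
#' @export
nearest_psd <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(pmax(diag(R), .Machine$double.eps))
  R <- R / outer(d, d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Configuration for the correlated-trajectory generator
#'
#' Describes a synthetic two-chain Calpha trajectory with planted
#' correlation structure: community blocks of residues moving in concert
#' (intra-block correlation `rho_in`), a weak background correlation
#' between all other pairs, and an optional planted high-correlation path
#' (consecutive node pairs at `rho_path`) emulating a dominant
#' force-propagation route. Displacements are isotropic Gaussian with
#' per-axis SD `fluctuation_sd` around the reference geometry.
#'
#' @param n_residues_per_chain residues per chain (two chains).
#' @param n_frames frames to sample (>= 2).
#' @param community_blocks list of lists, each with `nodes` (global node
#'   indices) and `rho` (intra-block correlation, |rho| <= 1). Default:
#'   each chain is one block at rho 0.6.
#' @param background_correlation correlation between unrelated pairs.
#' @param planted_path list with `nodes` (ordered node indices) and `rho`,
#'   or `NULL`.
#' @param fluctuation_sd per-axis displacement SD in A (0 is degenerate:
#'   all frames identical, flagged downstream).
#' @param contact_geometry list with `coords` and `topology` as from
#'   [make_two_chain_reference]; `NULL` uses the default layout.
#' @param repair_tol maximum tolerated elementwise change of the target
#'   correlation under PSD repair before a config error is raised.
#' @param seed integer RNG seed.
#' @return object of class `traj_gen_config`.
#' @export
traj_gen_config <- function(n_residues_per_chain = 20,
                            n_frames = 2000,
                            community_blocks = NULL,
                            background_correlation = 0.05,
                            planted_path = NULL,
                            fluctuation_sd = 1.0,
                            contact_geometry = NULL,
                            repair_tol = 0.1,
                            seed = 1) {
  stopifnot(n_residues_per_chain >= 2, n_frames >= 2,
            abs(background_correlation) <= 1, fluctuation_sd >= 0)
  n <- 2 * n_residues_per_chain
  if (is.null(contact_geometry)) {
    contact_geometry <- make_two_chain_reference(n_residues_per_chain)
  }
  stopifnot(nrow(contact_geometry$coords) == n)
  if (is.null(community_blocks)) {
    community_blocks <- list(
      list(nodes = 1:n_residues_per_chain, rho = 0.6),
      list(nodes = (n_residues_per_chain + 1):n, rho = 0.6))
  }
  for (b in community_blocks) {
    stopifnot(all(b$nodes >= 1), all(b$nodes <= n), abs(b$rho) <= 1)
  }
  if (!is.null(planted_path)) {
    stopifnot(all(planted_path$nodes >= 1), all(planted_path$nodes <= n),
              abs(planted_path$rho) <= 1)
  }
  structure(list(n_residues_per_chain = n_residues_per_chain,
                 n_frames = n_frames, community_blocks = community_blocks,
                 background_correlation = background_correlation,
                 planted_path = planted_path,
                 fluctuation_sd = fluctuation_sd,
                 contact_geometry = contact_geometry,
                 repair_tol = repair_tol, seed = as.integer(seed)),
            class = "traj_gen_config")
}

#' Construct a trajectory ensemble
#'
#' The package's container for Calpha coordinate trajectories: a topology
#' table (one row per residue: chain id and residue number) plus a frame
#' array, with declared coordinate units.
#'
#' @param coords array `n_frames x n_nodes x 3`.
#' @param topology data.frame with columns `node`, `chain`, `resno`.
#' @param units `"angstrom"` or `"nm"` (must be declared).
#' @param truth optional ground-truth list from a generator.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(coords, topology, units, truth = NULL) {
  if (missing(units) || !units %in% c("angstrom", "nm")) {
    stop("coordinate units must be declared as 'angstrom' or 'nm'")
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] >= 1,
            nrow(topology) == dim(coords)[2],
            all(c("node", "chain", "resno") %in% names(topology)))
  structure(list(coords = coords, topology = topology, units = units,
                 truth = truth, aligned = FALSE),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d frames, %d residues (%s), units %s%s\n",
              dim(x$coords)[1], dim(x$coords)[2],
              paste(unique(x$topology$chain), collapse = "+"),
              x$units, if (x$aligned) ", aligned" else ""))
  invisible(x)
}

#' Generate a correlated Calpha trajectory with planted ground truth
#'
#' Builds the target residue-residue correlation matrix from the
#' background, block and path specifications, repairs it to the nearest
#' positive semi-definite correlation (eigenvalue clipping), and samples
#' each coordinate axis independently from a multivariate Gaussian with
#' that correlation, scaled by `fluctuation_sd`, around the reference
#' geometry. The planted blocks, path, and repaired target matrix are
#' stored as ground truth.
#'
#' @param cfg a [traj_gen_config].
#' @return a [trajectory_ensemble] (units A) with `truth` containing
#'   `blocks`, `path`, `C_target`, `fluctuation_sd`, `degenerate`.
#' @export
gen_trajectory <- function(cfg) {
  stopifnot(inherits(cfg, "traj_gen_config"))
  set.seed(cfg$seed)
  n <- 2 * cfg$n_residues_per_chain
  C <- matrix(cfg$background_correlation, n, n)
  for (b in cfg$community_blocks) C[b$nodes, b$nodes] <- b$rho
  if (!is.null(cfg$planted_path)) {
    # Markov-consistent chain: correlation decays geometrically with path
    # distance, which keeps the planted block positive semi-definite
    pn <- cfg$planted_path$nodes
    for (k in seq_along(pn)) {
      for (l in seq_along(pn)) {
        if (k != l) {
          r <- cfg$planted_path$rho^abs(k - l)
          if (r > C[pn[k], pn[l]]) C[pn[k], pn[l]] <- C[pn[l], pn[k]] <- r
        }
      }
    }
  }
  diag(C) <- 1
  Cr <- nearest_psd(C)
  if (max(abs(Cr - C)) > cfg$repair_tol) {
    stop(sprintf(paste0("gen_trajectory: correlation structure infeasible; ",
                        "PSD repair changed entries by up to %.3f ",
                        "(tolerance %.3f)"),
                 max(abs(Cr - C)), cfg$repair_tol))
  }
  ref <- cfg$contact_geometry$coords
  coords <- array(0, c(cfg$n_frames, n, 3))
  if (cfg$fluctuation_sd > 0) {
    e <- eigen(Cr, symmetric = TRUE)
    B <- e$vectors %*% diag(sqrt(pmax(e$values, 0)))
    for (ax in 1:3) {
      Z <- matrix(stats::rnorm(cfg$n_frames * n), cfg$n_frames, n)
      disp <- cfg$fluctuation_sd * (Z %*% t(B))
      coords[, , ax] <- matrix(ref[, ax], cfg$n_frames, n, byrow = TRUE) + disp
    }
  } else {
    for (ax in 1:3) {
      coords[, , ax] <- matrix(ref[, ax], cfg$n_frames, n, byrow = TRUE)
    }
  }
  out <- trajectory_ensemble(
    coords, cfg$contact_geometry$topology, "angstrom",
    truth = list(blocks = cfg$community_blocks,
                 path = cfg$planted_path,
                 C_target = Cr,
                 fluctuation_sd = cfg$fluctuation_sd,
                 degenerate = cfg$fluctuation_sd == 0))
  # frames are sampled in a common reference frame (no rigid-body
  # diffusion is generated), so the ensemble is born aligned; running
  # superposition would strip the common-mode part of the planted
  # correlation field
  out$aligned <- TRUE
  out
}
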