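# Kabsch rigid-body superposition of frame X (n x 3) onto reference Y,
# both already centred. Returns the rotated X.
.kabsch <- function(X, Y) {
  S <- svd(crossprod(X, Y))
  d <- sign(det(S$v %*% t(S$u)))
  R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  X %*% t(R)
}

#' Rigid-body superposition of a trajectory onto its mean structure
#'
#' Least-squares (Kabsch) superposition of every frame onto the
#' iteratively refined mean Calpha structure: frames are centred, rotated
#' onto the current mean, the mean is recomputed, and the cycle repeats
#' until the mean moves by less than `tol` (RMS) or `max_iter` is hit.
#' Required before any fluctuation statistic (RMSF, correlation).
#'
#' @param ens a [trajectory_ensemble] (>= 2 frames).
#' @param max_iter maximum refinement cycles.
#' @param tol RMS convergence threshold on the mean structure (same units
#'   as the coordinates).
#' @return the aligned [trajectory_ensemble] (`aligned = TRUE`), with the
#'   mean structure attached as `mean_structure`.
#' @export
superpose <- function(ens, max_iter = 10, tol = 1e-6) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  nf <- dim(ens$coords)[1]
  n <- dim(ens$coords)[2]
  frames <- lapply(seq_len(nf), function(f) {
    X <- ens$coords[f, , ]
    sweep(X, 2, colMeans(X))
  })
  sv <- svd(frames[[1]])$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) {
    stop("superpose: degenerate (collinear) reference structure")
  }
  ref <- frames[[1]]
  for (it in seq_len(max_iter)) {
    frames <- lapply(frames, .kabsch, Y = ref)
    new_ref <- Reduce(`+`, frames) / nf
    shift <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (shift < tol) break
  }
  coords <- array(0, dim(ens$coords))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  out <- trajectory_ensemble(coords, ens$topology, ens$units, ens$truth)
  out$aligned <- TRUE
  out$mean_structure <- ref
  out
}

#' Root-mean-square fluctuation per residue
#'
#' `RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)` over an aligned ensemble.
#'
#' @param ens an aligned [trajectory_ensemble] (see [superpose]).
#' @param selection node indices (default all).
#' @return data.frame with `node`, `chain`, `resno`, `rmsf` (coordinate
#'   units).
#' @export
rmsf <- function(ens, selection = NULL) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (!isTRUE(ens$aligned)) {
    warning("ensemble is not aligned; RMSF includes rigid-body motion")
  }
  n <- dim(ens$coords)[2]
  if (is.null(selection)) selection <- seq_len(n)
  vals <- vapply(selection, function(i) {
    X <- ens$coords[, i, , drop = TRUE]
    mu <- colMeans(X)
    sqrt(mean(rowSums(sweep(X, 2, mu)^2)))
  }, numeric(1))
  data.frame(node = selection,
             chain = ens$topology$chain[selection],
             resno = ens$topology$resno[selection],
             rmsf = vals)
}

#' Residue-pair contact occupancy
#'
#' Occupancy(i,j) = fraction of frames in which residues i and j are
#' within `cutoff`. The canonical criterion uses heavy-atom distances at
#' 4.5 A; for Calpha-only ensembles (the synthetic case) the calculation
#' falls back to Calpha distances with a scaled cutoff (default 8.5 A)
#' and declares the fallback in the result attributes.
#'
#' @param ens a [trajectory_ensemble] with declared units.
#' @param cutoff heavy-atom contact cutoff in A (default 4.5).
#' @param ca_cutoff Calpha fallback cutoff in A (default 8.5).
#' @return symmetric `n x n` occupancy matrix in \[0,1\] with attributes
#'   `cutoff_used` and `mode` (`"calpha_fallback"`).
#' @export
contact_occupancy <- function(ens, cutoff = 4.5, ca_cutoff = 8.5) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  if (is.null(ens$units)) stop("coordinate units undeclared")
  scale <- if (ens$units == "nm") 10 else 1    # internally in A
  used <- ca_cutoff                             # Calpha-only ensembles
  nf <- dim(ens$coords)[1]
  n <- dim(ens$coords)[2]
  occ <- matrix(0, n, n)
  for (f in seq_len(nf)) {
    D <- as.matrix(stats::dist(ens$coords[f, , ] * scale))
    occ <- occ + (D < used)
  }
  occ <- occ / nf
  diag(occ) <- 1
  attr(occ, "cutoff_used") <- used
  attr(occ, "mode") <- "calpha_fallback"
  attr(occ, "heavy_atom_cutoff") <- cutoff
  occ
}

#' Dynamical cross-correlation matrix of Calpha displacements
#'
#' `c_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` with
#' `dr = r - <r>`, averaged over frames of an aligned ensemble.
#'
#' @param ens an aligned [trajectory_ensemble] with >= 10 frames.
#' @return symmetric matrix of correlations in \[-1,1\]; residues with
#'   zero variance give `NA` rows/columns and are flagged via the
#'   `zero_variance` attribute.
#' @export
correlation_matrix <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  nf <- dim(ens$coords)[1]
  if (nf < 10) stop("correlation_matrix: need at least 10 frames")
  if (!isTRUE(ens$aligned)) {
    warning("ensemble is not aligned; correlations include rigid-body motion")
  }
  n <- dim(ens$coords)[2]
  # centred displacement matrices per axis: frames x nodes
  dx <- lapply(1:3, function(ax) {
    X <- ens$coords[, , ax]
    sweep(X, 2, colMeans(X))
  })
  cross <- Reduce(`+`, lapply(dx, crossprod)) / nf   # <dr_i . dr_j>
  v <- diag(cross)
  zero <- v <= .Machine$double.eps
  denom <- sqrt(outer(v, v))
  C <- cross / denom
  C[zero, ] <- NA_real_
  C[, zero] <- NA_real_
  diag(C)[!zero] <- 1
  attr(C, "zero_variance") <- which(zero)
  C
}

#' Interdomain angle series and distribution peak
#'
#' Per frame, the angle between the dominant principal axes of the two
#' domains' Calpha clouds, each axis oriented to point from the partner
#' domain's centroid outward through its own. With this convention two
#' collinear domains (a straight rod) give 180 degrees and perpendicular
#' domains give 90 degrees. Frame-to-frame continuity is enforced by
#' flipping an axis when it reverses against the previous frame.
#'
#' @param ens an aligned [trajectory_ensemble].
#' @param domainA,domainB node indices of the two domains (>= 4 each).
#' @param bin_width histogram bin width in degrees for the peak fit.
#' @return list with `angles` (per-frame, degrees), `peak` (Gaussian peak,
#'   degrees), `sigma`, `method`, `degenerate` (TRUE when a domain cloud
#'   is effectively isotropic).
#' @export
interdomain_angle <- function(ens, domainA, domainB, bin_width = 2) {
  stopifnot(inherits(ens, "trajectory_ensemble"),
            length(domainA) >= 4, length(domainB) >= 4)
  nf <- dim(ens$coords)[1]
  angles <- numeric(nf)
  degenerate <- FALSE
  prevA <- prevB <- NULL
  for (f in seq_len(nf)) {
    XA <- ens$coords[f, domainA, ]
    XB <- ens$coords[f, domainB, ]
    cA <- colMeans(XA); cB <- colMeans(XB)
    sA <- svd(sweep(XA, 2, cA)); sB <- svd(sweep(XB, 2, cB))
    if (sA$d[1] < 1.2 * sA$d[2] || sB$d[1] < 1.2 * sB$d[2]) {
      degenerate <- TRUE
    }
    uA <- sA$v[, 1]; uB <- sB$v[, 1]
    # orient each axis outward: away from the partner domain's centroid
    if (sum(uA * (cA - cB)) < 0) uA <- -uA
    if (sum(uB * (cB - cA)) < 0) uB <- -uB
    # continuity guard against flips when the outward projection is tiny
    if (!is.null(prevA) && sum(uA * prevA) < 0 &&
        abs(sum(uA * (cA - cB))) < 1e-8) uA <- -uA
    if (!is.null(prevB) && sum(uB * prevB) < 0 &&
        abs(sum(uB * (cB - cA))) < 1e-8) uB <- -uB
    prevA <- uA; prevB <- uB
    angles[f] <- acos(max(-1, min(1, sum(uA * uB)))) * 180 / pi
  }
  if (degenerate) {
    warning("interdomain_angle: near-isotropic domain cloud; angle ill-defined")
  }
  pk <- tryCatch(gauss_peak(angles, bin_width = bin_width),
                 warning = function(w) {
                   suppressWarnings(gauss_peak(angles, bin_width = bin_width))
                 })
  list(angles = angles, peak = pk$mu, sigma = pk$sigma,
       method = pk$method, degenerate = degenerate)
}
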