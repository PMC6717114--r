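# File formats. All writers stamp a format_version; readers reject
# unknown major versions. Units: pN, nm, s, K internally; trajectory
# coordinates carry a declared unit.

.FORMAT_VERSION <- "1.0"

.check_format_version <- function(v, what) {
  if (is.null(v)) stop(what, ": missing format_version")
  major <- strsplit(as.character(v), ".", fixed = TRUE)[[1]][1]
  if (major != strsplit(.FORMAT_VERSION, ".", fixed = TRUE)[[1]][1]) {
    stop(sprintf("%s: unsupported format_version %s", what, v))
  }
}

#' Write a force-curve set to a directory
#'
#' One CSV per curve (`time_s`, `piezo_nm`, `force_pN`) plus a JSON
#' manifest (`manifest.json`) carrying the instrument metadata (kc,
#' velocity, temperature), ground-truth labels when present, and the
#' generator seed.
#'
#' @param curves a `force_curve_set` or list of `force_curve`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_force_curves <- function(curves, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(curves, "config")
  entries <- lapply(seq_along(curves), function(i) {
    ci <- curves[[i]]
    file <- sprintf("%s.csv", ci$id)
    utils::write.csv(as.data.frame(ci), file.path(dir, file),
                     row.names = FALSE)
    ent <- list(file = file, id = ci$id, kc = ci$kc,
                velocity = ci$velocity, temperature = ci$temperature)
    if (!is.null(ci$truth)) {
      ent$label <- ci$truth$label
      ent$rupture_force <- ci$truth$rupture_force
    }
    ent
  })
  manifest <- list(format_version = .FORMAT_VERSION,
                   type = "force_curves",
                   n_curves = length(curves),
                   seed = if (!is.null(cfg)) cfg$seed else NULL,
                   curves = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a force-curve set from a directory
#'
#' Validates the manifest and every per-curve file. Curves without `kc`
#' or `velocity` are a hard error (the mechanics are undefined without
#' them); curves with non-monotone time are rejected with a diagnostic
#' naming the file.
#'
#' @param dir directory written by [write_force_curves].
#' @return a `force_curve_set`.
#' @export
read_force_curves <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("read_force_curves: no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  .check_format_version(manifest$format_version, "read_force_curves")
  curves <- lapply(manifest$curves, function(ent) {
    path <- file.path(dir, ent$file)
    if (!file.exists(path)) {
      stop("read_force_curves: manifest names missing file ", ent$file)
    }
    if (is.null(ent$kc) || is.null(ent$velocity)) {
      stop("read_force_curves: curve ", ent$id,
           " lacks kc or velocity; physics undefined")
    }
    tab <- utils::read.csv(path)
    need <- c("time_s", "piezo_nm", "force_pN")
    if (!all(need %in% names(tab))) {
      stop("read_force_curves: ", ent$file, " lacks columns ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
    if (any(diff(tab$time_s) <= 0)) {
      stop("read_force_curves: non-monotone time in ", ent$file)
    }
    truth <- if (!is.null(ent$label)) {
      list(label = ent$label,
           rupture_force = if (is.null(ent$rupture_force)) NA_real_
                           else ent$rupture_force)
    } else NULL
    .new_force_curve(tab$time_s, tab$piezo_nm, tab$force_pN,
                     ent$kc, ent$velocity,
                     if (is.null(ent$temperature)) 298 else ent$temperature,
                     ent$id, truth)
  })
  structure(curves, class = "force_curve_set")
}

#' Write FRET traces to a directory
#'
#' One CSV per trace (`frame`, `I_D`, `I_A`) plus a JSON manifest with
#' the correction parameters of the generating config when available.
#'
#' @param traces a `fret_trace_set` or list of [fret_trace].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_fret_traces <- function(traces, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(traces, "config")
  entries <- lapply(traces, function(tr) {
    file <- sprintf("%s.csv", tr$trace_id)
    utils::write.csv(data.frame(frame = seq_along(tr$I_D),
                                I_D = tr$I_D, I_A = tr$I_A),
                     file.path(dir, file), row.names = FALSE)
    list(file = file, id = tr$trace_id)
  })
  manifest <- list(format_version = .FORMAT_VERSION, type = "fret_traces",
                   n_traces = length(traces),
                   correction = if (!is.null(cfg)) list(
                     background_donor = cfg$background_donor,
                     background_acceptor = cfg$background_acceptor,
                     leakage_alpha = cfg$leakage_alpha) else NULL,
                   seed = if (!is.null(cfg)) cfg$seed else NULL,
                   traces = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read FRET traces from a directory
#'
#' @param dir directory written by [write_fret_traces].
#' @return a `fret_trace_set`; the manifest's correction parameters (if
#'   any) are attached as attribute `correction`.
#' @export
read_fret_traces <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("read_fret_traces: no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  .check_format_version(manifest$format_version, "read_fret_traces")
  traces <- lapply(manifest$traces, function(ent) {
    path <- file.path(dir, ent$file)
    if (!file.exists(path)) {
      stop("read_fret_traces: manifest names missing file ", ent$file)
    }
    tab <- utils::read.csv(path)
    fret_trace(tab$I_D, tab$I_A, ent$id)
  })
  out <- structure(traces, class = "fret_trace_set")
  if (!is.null(manifest$correction)) {
    attr(out, "correction") <- manifest$correction
  }
  out
}

#' Write a trajectory ensemble as plain text
#'
#' Documented single-file fallback format for coordinate trajectories:
#' a tab-separated table (`frame`, `node`, `chain`, `resno`, `x`, `y`,
#' `z`) preceded by comment lines declaring the format version and
#' coordinate units. Round trips losslessly to 1e-6.
#'
#' @param ens a [trajectory_ensemble].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_trajectory_text <- function(ens, path) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  nf <- dim(ens$coords)[1]; n <- dim(ens$coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tiplinkmech-traj format_version %s",
                       .FORMAT_VERSION),
               sprintf("# units %s", ens$units),
               sprintf("# n_frames %d n_nodes %d", nf, n)), con)
  tab <- do.call(rbind, lapply(seq_len(nf), function(f) {
    data.frame(frame = f, node = ens$topology$node,
               chain = ens$topology$chain, resno = ens$topology$resno,
               x = ens$coords[f, , 1], y = ens$coords[f, , 2],
               z = ens$coords[f, , 3])
  }))
  utils::write.table(format(tab, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text trajectory file
#'
#' @param path file written by [write_trajectory_text].
#' @return a [trajectory_ensemble].
#' @export
read_trajectory_text <- function(path) {
  if (!file.exists(path)) stop("read_trajectory_text: no such file ", path)
  hdr <- readLines(path, n = 3)
  if (!grepl("^# tiplinkmech-traj format_version", hdr[1])) {
    stop("read_trajectory_text: not a tiplinkmech trajectory file")
  }
  .check_format_version(sub(".*format_version ", "", hdr[1]),
                        "read_trajectory_text")
  units <- sub("^# units ", "", hdr[2])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  frames <- sort(unique(tab$frame))
  first <- tab[tab$frame == frames[1], ]
  topology <- data.frame(node = first$node, chain = as.character(first$chain),
                         resno = first$resno)
  n <- nrow(topology)
  coords <- array(0, c(length(frames), n, 3))
  for (k in seq_along(frames)) {
    g <- tab[tab$frame == frames[k], ]
    if (nrow(g) != n) {
      stop("read_trajectory_text: frame ", frames[k], " has ", nrow(g),
           " atoms, expected ", n)
    }
    coords[k, , ] <- as.matrix(g[, c("x", "y", "z")])
  }
  trajectory_ensemble(coords, topology, units)
}

#' Read a trajectory from a topology file plus frames
#'
#' Accepts either a single plain-text trajectory file, or a PDB reference
#' (read via the bio3d package when installed) whose Calpha records
#' supply chain ids and residue numbers, combined with frame coordinates
#' from a plain-text trajectory file. Atom counts of topology and frames
#' must agree. PDB coordinates are in A; the plain-text format declares
#' its own units.
#'
#' @param top_path topology: `.pdb` file or plain-text trajectory.
#' @param traj_path frames: plain-text trajectory file, or `NULL` when
#'   `top_path` already carries frames.
#' @return a [trajectory_ensemble].
#' @export
read_trajectory <- function(top_path, traj_path = NULL) {
  if (grepl("\\.pdb$", top_path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("read_trajectory: reading PDB files requires the bio3d package")
    }
    pdb <- bio3d::read.pdb(top_path)
    ca <- bio3d::atom.select(pdb, "calpha")
    at <- pdb$atom[ca$atom, ]
    topology <- data.frame(node = seq_len(nrow(at)),
                           chain = as.character(at$chain),
                           resno = at$resno)
    if (is.null(traj_path)) {
      coords <- array(0, c(1, nrow(at), 3))
      coords[1, , ] <- as.matrix(at[, c("x", "y", "z")])
      return(trajectory_ensemble(coords, topology, "angstrom"))
    }
    ens <- read_trajectory_text(traj_path)
    if (dim(ens$coords)[2] != nrow(topology)) {
      stop(sprintf(paste0("read_trajectory: atom-count mismatch: ",
                          "topology has %d Calpha, frames have %d"),
                   nrow(topology), dim(ens$coords)[2]))
    }
    return(trajectory_ensemble(ens$coords, topology, ens$units))
  }
  ens <- read_trajectory_text(top_path)
  if (!is.null(traj_path) && traj_path != top_path) {
    frames <- read_trajectory_text(traj_path)
    if (dim(frames$coords)[2] != dim(ens$coords)[2]) {
      stop("read_trajectory: atom-count mismatch between topology and frames")
    }
    ens <- trajectory_ensemble(frames$coords, ens$topology, frames$units)
  }
  ens
}
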