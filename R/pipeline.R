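#' Run configuration for end-to-end pipelines
#'
#' A validated container of stage selection and stage parameters. Every
#' random stage carries an explicit seed (a stage without one inherits
#' `seed`). Unknown keys are rejected so that typos cannot silently
#' change a run.
#'
#' @param stages character vector drawn from `simulate_curves`,
#'   `analyze_smfs`, `simulate_traces`, `analyze_fret`,
#'   `simulate_trajectory`, `network`.
#' @param out_dir output directory for stage artifacts (`NULL`: nothing
#'   written).
#' @param seed default seed for stages without their own.
#' @param curves,smfs,traces,fret,trajectory,network named lists of
#'   arguments for the corresponding stage (see [curve_gen_config],
#'   [classify_criteria], [trace_gen_config], [analyze_fret_traces],
#'   [traj_gen_config], [suboptimal_paths]).
#' @return object of class `run_config`.
#' @export
run_config <- function(stages = character(0), out_dir = NULL, seed = 1,
                       curves = list(), smfs = list(), traces = list(),
                       fret = list(), trajectory = list(),
                       network = list()) {
  known <- c("simulate_curves", "analyze_smfs", "simulate_traces",
             "analyze_fret", "simulate_trajectory", "network")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) {
    stop("run_config: unknown stage(s): ", paste(bad, collapse = ", "))
  }
  structure(list(stages = stages, out_dir = out_dir, seed = as.integer(seed),
                 curves = curves, smfs = smfs, traces = traces,
                 fret = fret, trajectory = trajectory, network = network),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys must match the arguments of [run_config]; anything
#' else is rejected.
#'
#' @param path YAML file.
#' @return a [run_config].
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("read_run_config requires the yaml package")
  }
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("read_run_config: unknown key(s): ", paste(bad, collapse = ", "))
  }
  do.call(run_config, raw)
}

.stage_seed <- function(params, default) {
  if (!is.null(params$seed)) params$seed else default
}

#' Execute a configured pipeline end to end
#'
#' Runs the requested stages in dependency order
#' (simulate -> analyze -> network), writing artifacts under `out_dir`
#' when set, and returns a run report with per-stage summaries, the
#' package version, a config echo and wall time. A rerun with the same
#' config and seed reproduces the numeric report exactly (timestamps
#' aside). A stage failure aborts with the failing stage named; artifacts
#' of completed stages are retained.
#'
#' @param cfg a [run_config] (or path to a YAML file).
#' @return object of class `run_report`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  order <- c("simulate_curves", "analyze_smfs", "simulate_traces",
             "analyze_fret", "simulate_trajectory", "network")
  stages <- order[order %in% cfg$stages]
  out <- list()
  state <- new.env(parent = emptyenv())
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  for (st in stages) {
    res <- tryCatch(switch(
      st,
      simulate_curves = {
        args <- cfg$curves
        args$seed <- .stage_seed(cfg$curves, cfg$seed)
        state$curves <- gen_force_curves(do.call(curve_gen_config, args))
        if (!is.null(cfg$out_dir)) {
          write_force_curves(state$curves, file.path(cfg$out_dir, "curves"))
        }
        labs <- vapply(state$curves, function(ci) ci$truth$label,
                       character(1))
        list(n_curves = length(state$curves),
             n_specific_truth = sum(labs == "specific"),
             seed = args$seed)
      },
      analyze_smfs = {
        if (is.null(state$curves)) {
          stop("analyze_smfs requires simulate_curves (or preloaded curves)")
        }
        crit <- do.call(classify_criteria, cfg$smfs)
        ana <- dfs_analysis(state$curves, crit)
        if (!is.null(cfg$out_dir)) {
          utils::write.csv(ana$events,
                           file.path(cfg$out_dir, "smfs_events.csv"),
                           row.names = FALSE)
          utils::write.csv(ana$points,
                           file.path(cfg$out_dir, "smfs_points.csv"),
                           row.names = FALSE)
        }
        list(n_events = sum(ana$events$label == "specific"),
             specific_fraction = ana$specific_fraction,
             koff0 = ana$bell$koff0, x_beta = ana$bell$x_beta,
             se_koff0 = ana$bell$se$koff0, se_x_beta = ana$bell$se$x_beta)
      },
      simulate_traces = {
        args <- cfg$traces
        args$seed <- .stage_seed(cfg$traces, cfg$seed)
        state$traces <- gen_fret_traces(do.call(trace_gen_config, args))
        if (!is.null(cfg$out_dir)) {
          write_fret_traces(state$traces, file.path(cfg$out_dir, "traces"))
        }
        list(n_traces = length(state$traces), seed = args$seed)
      },
      analyze_fret = {
        if (is.null(state$traces)) {
          stop("analyze_fret requires simulate_traces (or preloaded traces)")
        }
        ana <- do.call(analyze_fret_traces,
                       c(list(traces = state$traces), cfg$fret))
        if (!is.null(cfg$out_dir)) {
          utils::write.csv(ana$efficiencies,
                           file.path(cfg$out_dir, "fret_efficiencies.csv"),
                           row.names = FALSE)
        }
        list(E_mp = ana$peak$E_mp, E_sigma = ana$peak$E_sigma,
             d_nm = ana$d_nm, n_rejected = ana$n_rejected)
      },
      simulate_trajectory = {
        args <- cfg$trajectory
        args$seed <- .stage_seed(cfg$trajectory, cfg$seed)
        state$traj <- gen_trajectory(do.call(traj_gen_config, args))
        if (!is.null(cfg$out_dir)) {
          write_trajectory_text(state$traj,
                                file.path(cfg$out_dir, "trajectory.tsv"))
        }
        list(n_frames = dim(state$traj$coords)[1],
             n_residues = dim(state$traj$coords)[2], seed = args$seed)
      },
      network = {
        if (is.null(state$traj)) {
          stop("network requires simulate_trajectory (or a preloaded ensemble)")
        }
        args <- cfg$network
        g <- residue_network(
          state$traj,
          occ_min = if (is.null(args$occ_min)) 0.75 else args$occ_min,
          trim_termini = if (is.null(args$trim_termini)) 3
                         else args$trim_termini)
        part <- communities_gn(g)
        summ <- list(n_nodes = igraph::vcount(g),
                     n_edges = igraph::ecount(g),
                     n_communities = part$n_communities,
                     modularity = part$modularity)
        if (!is.null(args$src) && !is.null(args$sink)) {
          ps <- suboptimal_paths(
            g, args$src, args$sink,
            edge_slack = if (is.null(args$edge_slack)) 20
                         else args$edge_slack)
          summ$optimal_weight <- ps$optimal$weight
          summ$n_suboptimal <- length(ps$paths)
          if (!is.null(cfg$out_dir)) {
            paths_tab <- data.frame(
              rank = seq_along(ps$paths),
              weight = ps$weights,
              n_edges = ps$n_edges,
              path = vapply(ps$paths, paste, character(1), collapse = "->"))
            utils::write.csv(paths_tab,
                             file.path(cfg$out_dir, "paths.csv"),
                             row.names = FALSE)
          }
        }
        summ
      }),
      error = function(e) {
        stop(sprintf("run_pipeline: stage '%s' failed: %s", st,
                     conditionMessage(e)), call. = FALSE)
      })
    out[[st]] <- res
  }
  structure(list(stages = out,
                 package_version =
                   as.character(utils::packageVersion("tiplinkmech")),
                 config = cfg,
                 wall_time_s = proc.time()[["elapsed"]] - t0),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (tiplinkmech %s), %.1f s, %d stage(s)\n",
              x$package_version, x$wall_time_s, length(x$stages)))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(names(s), vapply(s, function(v)
                  format(v, digits = 4), character(1)),
                  sep = "=", collapse = ", ")))
  }
  invisible(x)
}
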