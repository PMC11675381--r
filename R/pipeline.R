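#' Analysis configuration
#'
#' Collects every tunable of the full pipeline with defaults matching the
#' package's reference setting: inverse temperature \eqn{\beta = 0.534}
#' (bistable kite regime), coupling \eqn{J = 1}, lag horizon
#' \eqn{\tau_{\max} = 300}, 20% tail window for the asymptotic-information
#' estimate, 5-step tipping trajectories, and six-seed Monte Carlo
#' intervention runs.
#'
#' @param graph graph source: a fixture name (\code{"kite"}), a file path
#'   (edge list or GraphML), or an \code{igraph} object.
#' @param beta inverse temperature.
#' @param coupling ferromagnetic coupling \eqn{J}.
#' @param tau_max MI-curve lag horizon.
#' @param tail_fraction tail window for [estimate_omega()].
#' @param omega_mode \code{"shared"} or \code{"per-level"}.
#' @param path_length trajectory length for the path analysis.
#' @param horizon commitment-probability horizon.
#' @param sim_steps node-update attempts per intervention run.
#' @param sim_seeds seeds for the intervention runs.
#' @param out_dir output directory for [run_pipeline()].
#' @return a named list of class \code{analysis_config}.
#' @export
analysis_config <- function(graph = "kite", beta = 0.534, coupling = 1,
                            tau_max = 300, tail_fraction = 0.2,
                            omega_mode = "shared", path_length = 5,
                            horizon = 10, sim_steps = 2e5, sim_seeds = 1:6,
                            out_dir = "spinflow-results") {
  structure(
    list(graph = graph, beta = beta, coupling = coupling, tau_max = tau_max,
         tail_fraction = tail_fraction, omega_mode = omega_mode,
         path_length = path_length, horizon = horizon, sim_steps = sim_steps,
         sim_seeds = sim_seeds, out_dir = out_dir),
    class = "analysis_config"
  )
}

resolve_graph <- function(graph) {
  if (igraph::is_igraph(graph)) return(graph)
  if (identical(graph, "kite")) return(make_kite())
  if (is.character(graph) && file.exists(graph)) return(read_network(graph))
  stop(sprintf("unknown graph source: %s", format(graph)), call. = FALSE)
}

#' Run the full analysis pipeline and write results to disk
#'
#' Executes, in order: transfer-operator construction, stationary
#' distribution and free-energy profile, per-node per-level MI flow curves
#' with \eqn{\mu}/\eqn{\omega}/role assignment, tipping-trajectory
#' enumeration with maximisers, commitment probabilities, and the pinning
#' intervention experiment.  All outputs are written as tidy CSV/JSON files
#' plus a manifest recording inputs, seeds and output checksums; reruns with
#' the same configuration are byte-identical.
#'
#' @param config an [analysis_config()].
#' @param stages subset of
#'   \code{c("flows", "paths", "intervene")} to run (the exact build and
#'   stationary stage always runs); default all.
#' @param quiet suppress per-stage messages.
#' @return (invisibly) a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = analysis_config(),
                         stages = c("flows", "paths", "intervene"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  graph <- resolve_graph(config$graph)
  sys <- spin_system(graph, beta = config$beta, coupling = config$coupling)
  if (sys$n > 12) say("state space has 2^%d = %d states; exact stages may be slow",
                      sys$n, 2^sys$n)
  say("[build] transfer operator for n = %d (2^%d states)", sys$n, sys$n)
  op <- build_transfer_operator(sys)
  pi_hat <- stationary_distribution(op)
  profile <- free_energy_profile(pi_hat, op$space)
  files <- character(0)
  wr <- function(obj, name) {
    path <- file.path(config$out_dir, name)
    if (grepl("\\.csv$", name)) {
      utils::write.csv(obj, path, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    files <<- c(files, path)
    path
  }
  wr(data.frame(state_index = 0:(op$space$n_states - 1), probability = pi_hat),
     "stationary_distribution.csv")
  wr(profile, "free_energy_profile.csv")

  results <- list(system = sys, op = op, stationary = pi_hat,
                  free_energy = profile)

  if ("flows" %in% stages) {
    say("[flows] MI curves: %d nodes x %d levels x %d lags",
        sys$n, sum(gamma_levels(op$space) <= 0.5), config$tau_max)
    flows <- info_flow(sys, tau_max = config$tau_max,
                       tail_fraction = config$tail_fraction,
                       omega_mode = config$omega_mode, op = op)
    wr(mi_curve_table(flows), "mi_curves.csv")
    roles <- node_roles(flows)
    mu_long <- data.frame(
      node = rep(flows$nodes, times = length(flows$levels)),
      gamma = rep(flows$levels, each = length(flows$nodes)),
      mu = as.vector(flows$mu),
      omega_level = as.vector(flows$omega_by_level)
    )
    wr(mu_long, "integrated_mi.csv")
    wr(roles, "node_roles.csv")
    wr(list(omega_mode = flows$omega_mode,
            roles = roles), "roles_summary.json")
    results$flows <- flows
  }

  if ("paths" %in% stages) {
    say("[paths] enumerating %d-step trajectories to gamma = 0.5",
        config$path_length)
    trajs <- enumerate_tipping_trajectories(
      op, rep(0, sys$n), length = config$path_length, target_gamma = 0.5)
    best <- if (nrow(trajs$states) > 0) maximal_trajectories(trajs) else trajs
    traj_json <- lapply(seq_len(nrow(best$states)), function(i) {
      list(states = best$states[i, ], logp = best$step_logps[i, ],
           objective = best$objective[i])
    })
    wr(list(n_trajectories = nrow(trajs$states),
            n_maximal = nrow(best$states),
            max_objective = if (nrow(best$states) > 0) best$objective[1] else NULL,
            maximal = traj_json), "tipping_trajectories.json")
    if (nrow(best$states) > 0) {
      wr(trajectory_table(best, op$space, which = 1), "best_trajectory_states.csv")
    }
    if (sys$n %% 2 == 0) {
      commit <- do.call(rbind, lapply(0:(sys$n - 1), function(nd) {
        cbind(node = nd, commitment_probabilities(op, nd, config$horizon))
      }))
      wr(commit, "commitment_probabilities.csv")
      results$commitment <- commit
    }
    results$trajectories <- trajs
    results$maximal <- best
  }

  if ("intervene" %in% stages) {
    say("[intervene] pinning experiment: %g attempts x %d seeds",
        config$sim_steps, length(config$sim_seeds))
    roles_obj <- results$flows
    if (is.null(roles_obj)) {
      roles_obj <- info_flow(sys, tau_max = config$tau_max,
                             tail_fraction = config$tail_fraction,
                             omega_mode = config$omega_mode, op = op,
                             keep_curves = FALSE)
    }
    report <- intervention_experiment(sys, roles_obj,
                                      steps = config$sim_steps,
                                      seeds = config$sim_seeds)
    wr(report$per_run, "intervention_runs.csv")
    wr(report$summary, "intervention_summary.csv")
    results$intervention <- report
  }

  manifest <- list(
    package = "spinflow",
    version = as.character(utils::packageVersion("spinflow")),
    config = unclass(config)[setdiff(names(config), "graph")],
    graph = list(n = sys$n, edges = igraph::ecount(sys$graph),
                 source = if (is.character(config$graph)) config$graph else "igraph object"),
    stages = stages,
    n_states = op$space$n_states,
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(f) unname(tools::md5sum(f))),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[done] %d output files in %s", length(files) + 1, config$out_dir)
  results$manifest <- manifest
  invisible(results)
}
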