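#' Monte Carlo Glauber simulation, optionally with a pinned node
#'
#' Runs the asynchronous single-spin-flip chain of a [spin_system()] with a
#' compiled sampler.  Each step is one node-update attempt; the macrostate
#' \eqn{\langle S \rangle} is recorded once per sweep (every \code{n}
#' attempts), with a per-attempt trace available on request.  Pinning freezes
#' one node at a fixed state and removes it from the update pool — a causal
#' clamp: other nodes still feel the pinned state, but it never changes.
#'
#' Runs are bit-reproducible: the same system, step count, seed and pinning
#' give identical traces.
#'
#' @param system a [spin_system()].
#' @param steps number of node-update attempts, \code{>= 1}.
#' @param seed integer RNG seed.
#' @param pinned optional list or vector \code{c(node =, state =)} giving the
#'   node id to clamp (0-based) and its frozen state (0 or 1); \code{NULL}
#'   for no intervention.
#' @param initial starting configuration: a 0/1 vector, or \code{"random"}
#'   (each node Bernoulli(1/2)), or \code{"zero"} (the all-zero attractor,
#'   default).
#' @param record_attempts also keep the per-attempt macrostate trace.
#' @param track_states tally the empirical state-visit distribution (only for
#'   \code{n <= 14}); useful for checking convergence to the exact
#'   stationary distribution.
#' @return an object of class \code{simulation_run}: list with \code{trace}
#'   (per-sweep macrostates), \code{final_config}, \code{seed}, \code{pinned},
#'   and optionally \code{attempt_trace} and \code{visits}.
#' @examples
#' run <- simulate_glauber(spin_system(make_kite(), beta = 0.534),
#'                         steps = 1e4, seed = 1)
#' mean(run$trace)
#' @export
simulate_glauber <- function(system, steps, seed, pinned = NULL,
                             initial = "zero", record_attempts = FALSE,
                             track_states = FALSE) {
  stopifnot(inherits(system, "spin_system"))
  steps <- as.numeric(steps)
  if (length(steps) != 1 || is.na(steps) || steps < 1) {
    stop("`steps` must be >= 1", call. = FALSE)
  }
  pin_node <- -1L
  pin_state <- 0L
  if (!is.null(pinned)) {
    pinned <- unlist(pinned)
    if (is.null(names(pinned))) names(pinned) <- c("node", "state")[seq_along(pinned)]
    pin_node <- check_node(system, pinned[["node"]])
    pin_state <- as.integer(pinned[["state"]])
    if (!pin_state %in% c(0L, 1L)) stop("pinned state must be 0 or 1", call. = FALSE)
    if (system$n < 2) {
      stop("pinning is degenerate for a single-node system", call. = FALSE)
    }
  }
  if (track_states && system$n > 14) {
    stop("state tracking requires n <= 14", call. = FALSE)
  }
  adj_list <- lapply(igraph::adjacent_vertices(system$graph, igraph::V(system$graph)),
                     function(v) as.integer(v) - 1L)
  offset <- c(0L, cumsum(lengths(adj_list)))
  nbr <- as.integer(unlist(adj_list, use.names = FALSE))
  if (identical(initial, "random")) {
    set.seed(seed)
    init <- sample(c(0L, 1L), system$n, replace = TRUE)
  } else if (identical(initial, "zero")) {
    init <- rep(0L, system$n)
  } else {
    init <- check_config(system, initial)
  }
  if (pin_node >= 0) init[pin_node + 1L] <- pin_state
  set.seed(seed)
  raw <- .glauber_run(system$n, nbr, as.integer(offset), system$beta,
                      system$coupling, init, steps, pin_node,
                      record_attempts, track_states)
  structure(
    list(
      trace = raw$sweep_trace,
      attempt_trace = raw$attempt_trace,
      visits = raw$visits,
      final_config = raw$final_config,
      steps = steps,
      seed = seed,
      pinned = if (pin_node >= 0) c(node = pin_node, state = pin_state) else NULL,
      initial = init
    ),
    class = "simulation_run"
  )
}

#' @export
print.simulation_run <- function(x, ...) {
  cat(sprintf("<simulation_run> %g attempts (%d sweeps recorded), seed %d%s\n",
              x$steps, length(x$trace), x$seed,
              if (!is.null(x$pinned))
                sprintf(", node %d pinned to %d", x$pinned["node"], x$pinned["state"])
              else ""))
  invisible(x)
}

#' Count successful metastable transitions in a macrostate trace
#'
#' A successful transition is a crossing in which the macrostate moves from
#' strictly one side of the tipping level to strictly the other side; merely
#' touching the level and relaxing back does not count (hysteresis rule), so
#' grazes at \eqn{\langle S \rangle = 0.5} are never double-counted.
#'
#' @param run a [simulate_glauber()] result, or a bare numeric macrostate
#'   trace.
#' @param tipping the tipping level (default 0.5).
#' @return integer number of transitions.
#' @examples
#' count_transitions(c(0, 0.2, 0.5, 0.3, 0.6, 1, 0.4, 0.2))  # 2
#' @export
count_transitions <- function(run, tipping = 0.5) {
  trace <- if (inherits(run, "simulation_run")) run$trace else as.numeric(run)
  if (length(trace) == 0) stop("empty trace", call. = FALSE)
  side <- sign(trace - tipping)
  side <- side[side != 0]
  if (length(side) < 2) return(0L)
  sum(diff(side) != 0)
}

# Second central moment of the macrostate and fraction of time below tipping.
trace_metrics <- function(trace, tipping = 0.5) {
  c(second_moment = mean((trace - mean(trace))^2),
    time_below = mean(trace < tipping))
}

#' Pinning-intervention experiment on one system
#'
#' For each candidate pinned node — by default the top initiator and the top
#' stabilizer from an information-flow analysis — runs pinned-to-0
#' simulations alongside an unpinned control arm with matched seeds, and
#' reports the standard intervention metrics: the macrostate fluctuation
#' second moment and the time spent below the tipping point, both normalised
#' by the control (control ratios are 1 by construction), plus counts of
#' successful metastable transitions.
#'
#' @param system a [spin_system()].
#' @param roles an [info_flow()] result for \code{system}; may be \code{NULL}
#'   when \code{pin_nodes} is given explicitly.
#' @param steps node-update attempts per run.
#' @param seeds vector of RNG seeds (one run per seed per arm).
#' @param pin_nodes which nodes to pin: \code{"roles"} (top initiator and top
#'   stabilizer), \code{"all"}, or an integer vector of node ids.
#' @param initial starting configuration passed to [simulate_glauber()].
#' @return an object of class \code{intervention_report}: list with
#'   \code{per_run} (tidy data.frame keyed by arm × seed),
#'   \code{summary} (per-arm means and control-normalised ratios) and the
#'   pinned-node choices.
#' @export
intervention_experiment <- function(system, roles = NULL, steps = 2e5,
                                    seeds = 1:6, pin_nodes = "roles",
                                    initial = "zero") {
  stopifnot(inherits(system, "spin_system"))
  if (length(seeds) == 0) stop("`seeds` must be non-empty", call. = FALSE)
  if (identical(pin_nodes, "roles")) {
    if (!inherits(roles, "info_flow")) {
      stop("`roles` (an info_flow result) is required when pin_nodes = \"roles\"",
           call. = FALSE)
    }
    nodes <- c(initiator = roles$nodes[which.max(roles$role_score)],
               stabilizer = roles$nodes[which.min(roles$role_score)])
  } else if (identical(pin_nodes, "all")) {
    nodes <- 0:(system$n - 1)
    names(nodes) <- paste0("node", nodes)
  } else {
    nodes <- vapply(pin_nodes, check_node, integer(1), system = system)
    names(nodes) <- paste0("node", nodes)
  }
  arms <- c(list(control = NULL),
            stats::setNames(lapply(nodes, function(nd) c(node = nd, state = 0L)),
                            names(nodes)))
  rows <- list()
  for (arm in names(arms)) {
    for (sd in seeds) {
      run <- simulate_glauber(system, steps = steps, seed = sd,
                              pinned = arms[[arm]], initial = initial)
      m <- trace_metrics(run$trace)
      rows[[length(rows) + 1L]] <- data.frame(
        arm = arm,
        pinned_node = if (is.null(arms[[arm]])) NA_integer_ else arms[[arm]][["node"]],
        seed = sd,
        second_moment = m[["second_moment"]],
        time_below = m[["time_below"]],
        n_transitions = count_transitions(run)
      )
    }
  }
  per_run <- do.call(rbind, rows)
  agg <- stats::aggregate(per_run[c("second_moment", "time_below", "n_transitions")],
                          by = list(arm = per_run$arm), FUN = mean)
  ctrl <- agg[agg$arm == "control", ]
  agg$second_moment_ratio <- agg$second_moment / ctrl$second_moment
  agg$time_below_ratio <- agg$time_below / ctrl$time_below
  structure(
    list(per_run = per_run, summary = agg, pinned_nodes = nodes,
         steps = steps, seeds = seeds),
    class = "intervention_report"
  )
}

#' @export
print.intervention_report <- function(x, ...) {
  cat(sprintf("<intervention_report> %g attempts x %d seeds per arm\n",
              x$steps, length(x$seeds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Pinning interventions across an Erdős–Rényi ensemble
#'
#' Replicates the ensemble intervention protocol: draw connected
#' \eqn{G(n, p)} graphs, compute each graph's node roles with the exact
#' information-flow pipeline, then pin the top initiator and the top
#' stabilizer to state 0 and compare successful-transition counts against an
#' unpinned control, each graph normalised by its own control.
#'
#' @param n_graphs number of ER graphs (default 100).
#' @param n nodes per graph (default 10).
#' @param p edge probability (default 0.2).
#' @param beta inverse temperature (default 0.534).
#' @param steps node-update attempts per run.
#' @param seeds simulation seeds per arm (default \code{1:6}).
#' @param graph_seed base seed for graph sampling; graph \code{g} uses
#'   \code{graph_seed + g}.
#' @param tau_max lag horizon for the per-graph role computation.
#' @return an object of class \code{ensemble_report}: list with
#'   \code{per_graph} (one row per graph: transition means per arm and
#'   control-normalised ratios) and \code{sign_test}, the one-sided sign test
#'   that initiator-pinning yields at least as many transitions as
#'   stabilizer-pinning.
#' @export
er_intervention_ensemble <- function(n_graphs = 100, n = 10, p = 0.2,
                                     beta = 0.534, steps = 2e5, seeds = 1:6,
                                     graph_seed = 0, tau_max = 300) {
  rows <- list()
  for (g in seq_len(n_graphs)) {
    graph <- make_er(n, p, seed = graph_seed + g, require_connected = TRUE)
    sys <- spin_system(graph, beta = beta)
    flows <- info_flow(sys, tau_max = tau_max, keep_curves = FALSE)
    rep_g <- intervention_experiment(sys, flows, steps = steps, seeds = seeds)
    s <- rep_g$summary
    get <- function(arm, col) s[s$arm == arm, col]
    rows[[g]] <- data.frame(
      graph_id = g,
      initiator_node = rep_g$pinned_nodes[["initiator"]],
      stabilizer_node = rep_g$pinned_nodes[["stabilizer"]],
      transitions_control = get("control", "n_transitions"),
      transitions_initiator = get("initiator", "n_transitions"),
      transitions_stabilizer = get("stabilizer", "n_transitions"),
      second_moment_ratio_initiator = get("initiator", "second_moment_ratio"),
      second_moment_ratio_stabilizer = get("stabilizer", "second_moment_ratio"),
      time_below_ratio_initiator = get("initiator", "time_below_ratio"),
      time_below_ratio_stabilizer = get("stabilizer", "time_below_ratio")
    )
  }
  per_graph <- do.call(rbind, rows)
  diff <- per_graph$transitions_initiator - per_graph$transitions_stabilizer
  n_pos <- sum(diff > 0)
  n_eff <- sum(diff != 0)
  p_val <- if (n_eff == 0) 1 else
    stats::binom.test(n_pos, n_eff, alternative = "greater")$p.value
  structure(
    list(per_graph = per_graph,
         sign_test = list(n_positive = n_pos, n_nonzero = n_eff,
                          p_value = p_val)),
    class = "ensemble_report"
  )
}

#' @export
print.ensemble_report <- function(x, ...) {
  cat(sprintf(
    "<ensemble_report> %d graphs; initiator > stabilizer in %d/%d (sign test p = %.3g)\n",
    nrow(x$per_graph), x$sign_test$n_positive, x$sign_test$n_nonzero,
    x$sign_test$p_value))
  invisible(x)
}
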