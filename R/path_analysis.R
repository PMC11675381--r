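#' Enumerate single-flip trajectories to a magnetisation level
#'
#' Exhaustively lists every state sequence \eqn{S^0, \dots, S^L} that starts
#' at \code{start}, flips exactly one node per step, and ends at the target
#' level \eqn{\langle S^L \rangle = \gamma}.  Each trajectory is scored by its
#' summed log one-step transition probability
#' \eqn{\sum_t \log p(S^{t+1} \mid S^t)}, taken from the full transfer
#' operator (the \eqn{1/n} node-selection factor included).
#'
#' When the target requires exactly \code{length} flips the sequences contain
#' no stays and the count is purely combinatorial
#' (\eqn{n (n-1) \cdots (n-k+1)} from the all-zero state), independent of
#' \eqn{\beta}; \code{allow_stays} additionally admits self-loop steps for
#' slack queries (\code{length} larger than the flips needed).
#'
#' @param op a [build_transfer_operator()] result.
#' @param start starting configuration (0/1 vector) or a single state index.
#' @param length number of steps \eqn{L \ge 1}.
#' @param target_gamma magnetisation level of the final state.
#' @param allow_stays also allow self-loop (no-flip) steps.
#' @return an object of class \code{trajectory_set}: list with \code{states}
#'   (an \code{ntraj x (L+1)} matrix of 0-based state indices),
#'   \code{step_logps} (\code{ntraj x L}), \code{objective}
#'   (row sums of \code{step_logps}) and bookkeeping fields.  Zero matching
#'   sequences yield an empty (0-row) set, not an error.
#' @examples
#' op <- build_transfer_operator(spin_system(make_kite(), beta = 0.534))
#' trajs <- enumerate_tipping_trajectories(op, rep(0, 10), length = 5,
#'                                         target_gamma = 0.5)
#' nrow(trajs$states)  # 30240
#' @export
enumerate_tipping_trajectories <- function(op, start, length, target_gamma,
                                           allow_stays = FALSE) {
  stopifnot(inherits(op, "transfer_operator"))
  space <- op$space
  n <- space$n
  if (length < 1) stop("`length` must be >= 1", call. = FALSE)
  start_idx <- if (base::length(start) == n && all(start %in% c(0, 1))) {
    encode_state(space, start)
  } else if (base::length(start) == 1) {
    as.integer(start)
  } else {
    stop("`start` must be a 0/1 configuration of length n or a state index",
         call. = FALSE)
  }
  if (start_idx < 0 || start_idx >= space$n_states) {
    stop("`start` is not a valid state", call. = FALSE)
  }
  k_target <- target_gamma * n
  if (abs(k_target - round(k_target)) > 1e-9) {
    stop(sprintf("target gamma = %g is not attainable with n = %d nodes",
                 target_gamma, n), call. = FALSE)
  }
  k_target <- as.integer(round(k_target))

  # Depth-first enumeration over per-step moves (flip node 0..n-1, or stay),
  # pruned by reachability: the remaining steps must be able to bridge the
  # gap in 1-counts, with matching parity when stays are disallowed.
  moves <- if (allow_stays) c(0:(n - 1), -1L) else 0:(n - 1)
  paths <- list()
  n_paths <- 0L
  seq_buf <- integer(length)
  ones0 <- space$ones[start_idx + 1L]

  recurse <- function(state, ones, depth) {
    rem <- length - depth
    gap <- abs(k_target - ones)
    if (gap > rem) return(invisible())
    if (!allow_stays && (gap %% 2L) != (rem %% 2L)) return(invisible())
    if (depth == length) {
      n_paths <<- n_paths + 1L
      paths[[n_paths]] <<- seq_buf
      return(invisible())
    }
    for (mv in moves) {
      if (mv < 0) {
        seq_buf[depth + 1L] <<- -1L
        recurse(state, ones, depth + 1L)
      } else {
        nxt <- bitwXor(state, 2L^mv)
        seq_buf[depth + 1L] <<- mv
        recurse(nxt, space$ones[nxt + 1L], depth + 1L)
      }
    }
  }
  recurse(start_idx, ones0, 0L)

  if (n_paths == 0L) {
    return(empty_trajectory_set(start_idx, length, target_gamma))
  }
  flips <- do.call(rbind, paths[seq_len(n_paths)])

  # Rebuild state sequences and per-step log probabilities vectorised over
  # trajectories.
  states <- matrix(0L, nrow = n_paths, ncol = length + 1)
  states[, 1] <- start_idx
  logps <- matrix(0, nrow = n_paths, ncol = length)
  inv_n_log <- -log(n)
  for (t in seq_len(length)) {
    cur <- states[, t]
    mv <- flips[, t]
    stay <- mv < 0L
    nxt <- ifelse(stay, cur, bitwXor(cur, 2L^pmax(mv, 0L)))
    states[, t + 1] <- nxt
    lp <- numeric(n_paths)
    if (any(!stay)) {
      lp[!stay] <- log(op$flip_prob[cbind(cur[!stay] + 1L, mv[!stay] + 1L)]) +
        inv_n_log
    }
    if (any(stay)) {
      diag_mass <- 1 - rowSums(op$flip_prob[cur[stay] + 1L, , drop = FALSE]) / n
      lp[stay] <- log(diag_mass)
    }
    logps[, t] <- lp
  }
  structure(
    list(
      states = states,
      step_logps = logps,
      objective = rowSums(logps),
      start = start_idx,
      length = length,
      target_gamma = target_gamma,
      allow_stays = allow_stays
    ),
    class = "trajectory_set"
  )
}

empty_trajectory_set <- function(start_idx, length, target_gamma) {
  structure(
    list(
      states = matrix(integer(0), nrow = 0, ncol = length + 1),
      step_logps = matrix(numeric(0), nrow = 0, ncol = length),
      objective = numeric(0),
      start = start_idx, length = length, target_gamma = target_gamma,
      allow_stays = FALSE
    ),
    class = "trajectory_set"
  )
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d trajectories of %d steps to gamma = %g (start state %d)\n",
    nrow(x$states), x$length, x$target_gamma, x$start))
  if (nrow(x$states) > 0) {
    cat(sprintf("  objective range: [%.4f, %.4f] (log probability)\n",
                min(x$objective), max(x$objective)))
  }
  invisible(x)
}

#' Trajectories attaining the maximal log probability
#'
#' Selects the subset of a trajectory set whose objective lies within
#' \code{tie_tol} of the maximum.  In a symmetric graph the maximisers form a
#' tie class related by graph automorphisms, so ties are exact up to
#' round-off and a small absolute tolerance in log units suffices.
#'
#' @param trajectories a [enumerate_tipping_trajectories()] result.
#' @param tie_tol absolute tolerance in log-probability units.
#' @return a \code{trajectory_set} with the maximisers, sorted
#'   lexicographically by their state-index sequences.
#' @export
maximal_trajectories <- function(trajectories, tie_tol = 1e-9) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (nrow(trajectories$states) == 0) {
    stop("cannot take maximisers of an empty trajectory set", call. = FALSE)
  }
  best <- max(trajectories$objective)
  keep <- which(trajectories$objective >= best - tie_tol)
  ord <- do.call(order, as.data.frame(trajectories$states[keep, , drop = FALSE]))
  keep <- keep[ord]
  out <- trajectories
  out$states <- trajectories$states[keep, , drop = FALSE]
  out$step_logps <- trajectories$step_logps[keep, , drop = FALSE]
  out$objective <- trajectories$objective[keep]
  out
}

#' Attractor-commitment probabilities at the tipping point
#'
#' Starting from the stationary ensemble restricted to the tipping level
#' \eqn{\langle S \rangle = 0.5} and conditioning on a node's state there,
#' evolves the chain \code{horizon} steps and reports where the macrostate
#' ends up: above the tipping point, below it, or exactly on it.  A node whose
#' state at the tipping point agrees in sign with the future macrostate with
#' probability above one half is predictive of the attractor the system
#' commits to; a probability below one half means the system tends to settle
#' on the side opposite to the node's state.
#'
#' @param op a [build_transfer_operator()] result; \code{n} must be even so
#'   the tipping level is non-empty.
#' @param node integer node id in \code{0..n-1}.
#' @param horizon number of steps to evolve (default 10).
#' @return a data.frame with rows for node state \code{a = 0, 1} and columns
#'   \code{p_above}, \code{p_below}, \code{p_tie}
#'   (\eqn{P(\langle S^{h} \rangle \gtrless 0.5 \mid s_i^0 = a)}) and
#'   \code{p_agree}, the probability that the future macrostate sign matches
#'   the node's state.
#' @export
commitment_probabilities <- function(op, node, horizon = 10) {
  stopifnot(inherits(op, "transfer_operator"))
  node <- check_node(op$system, node)
  if (horizon < 1) stop("`horizon` must be >= 1", call. = FALSE)
  space <- op$space
  if (space$n %% 2L != 0L) {
    stop("the tipping level gamma = 0.5 is empty for odd n", call. = FALSE)
  }
  pi_hat <- stationary_distribution(op)
  level <- conditional_state_distribution(pi_hat, space, 0.5)
  joint <- joint_at_zero(space, level, node)
  p_a <- rowSums(joint)
  for (k in seq_len(horizon)) joint <- as.matrix(joint %*% op$matrix)
  half <- space$n / 2
  side <- sign(space$ones - half)       # -1 below, 0 tie, +1 above
  res <- data.frame(
    node_state = c(0L, 1L),
    p_above = c(sum(joint[1, side > 0]), sum(joint[2, side > 0])) / p_a,
    p_below = c(sum(joint[1, side < 0]), sum(joint[2, side < 0])) / p_a,
    p_tie = c(sum(joint[1, side == 0]), sum(joint[2, side == 0])) / p_a
  )
  res$p_agree <- ifelse(res$node_state == 1, res$p_above, res$p_below)
  res
}

#' Per-step node-state table of a trajectory
#'
#' Decodes one trajectory of a [enumerate_tipping_trajectories()] result into
#' a long table of node states per step, convenient for strip-style plots of
#' the flip cascade.
#'
#' @param trajectories a \code{trajectory_set}.
#' @param which row index of the trajectory to decode (default 1).
#' @param space the matching [state_space()].
#' @return a data.frame with columns \code{step}, \code{node}, \code{state}.
#' @export
trajectory_table <- function(trajectories, space, which = 1) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(space, "state_space"))
  if (which < 1 || which > nrow(trajectories$states)) {
    stop("`which` is out of range", call. = FALSE)
  }
  idx <- trajectories$states[which, ]
  cfg <- space$bits[idx + 1L, , drop = FALSE]
  data.frame(
    step = rep(0:(length(idx) - 1), each = space$n),
    node = rep(0:(space$n - 1), times = length(idx)),
    state = as.integer(t(cfg))
  )
}
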