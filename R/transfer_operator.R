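#' Exact single-step transfer operator of asynchronous Glauber dynamics
#'
#' Builds the row-stochastic \eqn{2^n \times 2^n} Markov matrix of the
#' single-spin-flip chain: at each discrete step one node is chosen uniformly
#' at random and flipped with its Glauber probability (see
#' [flip_probability()]).  Off-diagonal mass is therefore restricted to pairs
#' of states at Hamming distance 1,
#' \deqn{T[s, s \oplus e_i] = \frac{1}{n} \, P(\mathrm{flip}\ i \mid s),}
#' and the lazy diagonal \eqn{T[s, s] = 1 - \sum_{s' \ne s} T[s, s']} carries
#' the probability that the chosen node does not flip.
#'
#' @param system a [spin_system()].
#' @param cap state-space size guard passed to [state_space()].
#' @return an object of class \code{transfer_operator}: a list with the sparse
#'   matrix \code{matrix} (rows/columns ordered by state index), the
#'   \code{space}, the per-state energies \code{energy}, the \code{2^n x n}
#'   flip-probability matrix \code{flip_prob} (entry \code{[s + 1, i + 1]} is
#'   the probability that node \code{i} flips from state \code{s}, without the
#'   \code{1/n} selection factor), the originating \code{system} and the
#'   update-scheme tag.
#' @examples
#' op <- build_transfer_operator(spin_system(make_kite(), beta = 0.534))
#' range(Matrix::rowSums(op$matrix))  # rows sum to 1
#' @export
build_transfer_operator <- function(system, cap = 14) {
  stopifnot(inherits(system, "spin_system"))
  space <- state_space(system$n, cap = cap)
  n <- space$n
  sigma <- 2 * space$bits - 1                      # 2^n x n spin matrix
  el <- igraph::as_edgelist(system$graph, names = FALSE)
  e_all <- numeric(space$n_states)
  if (nrow(el) > 0) {
    for (e in seq_len(nrow(el))) {
      e_all <- e_all - system$coupling * sigma[, el[e, 1]] * sigma[, el[e, 2]]
    }
  }
  # field[s, i] = sum of neighbour spins of node i in state s
  field <- sigma %*% system$adj
  # energy released by flipping node i: -2 J sigma_i h_i
  delta_e <- -2 * system$coupling * sigma * field
  flip_prob <- 1 / (1 + exp(-system$beta * delta_e))

  idx <- 0:(space$n_states - 1)
  from <- rep(idx, times = n)
  to <- as.vector(vapply(0:(n - 1), function(b) bitwXor(idx, 2L^b),
                         integer(space$n_states)))
  p <- as.vector(flip_prob) / n
  diag_mass <- 1 - rowSums(flip_prob) / n
  mat <- Matrix::sparseMatrix(
    i = c(from, idx) + 1L,
    j = c(to, idx) + 1L,
    x = c(p, diag_mass),
    dims = c(space$n_states, space$n_states)
  )
  structure(
    list(
      matrix = mat,
      space = space,
      energy = e_all,
      flip_prob = flip_prob,
      system = system,
      update_scheme = "single-flip-random-node"
    ),
    class = "transfer_operator"
  )
}

#' @export
print.transfer_operator <- function(x, ...) {
  cat(sprintf("<transfer_operator> %d x %d (n = %d nodes), scheme = %s\n",
              x$space$n_states, x$space$n_states, x$space$n, x$update_scheme))
  invisible(x)
}

#' Stationary distribution of the Glauber chain
#'
#' Solves \eqn{\pi T = \pi}, \eqn{\sum \pi = 1} by a direct sparse linear
#' solve (one stationarity equation replaced by the normalisation).  The
#' direct solve is used because bistability makes the spectral gap tiny, so
#' power iteration converges impractically slowly near the interesting
#' parameter regime.
#'
#' Glauber dynamics is reversible, so \eqn{\pi} coincides with the Boltzmann
#' distribution \eqn{e^{-\beta E(S)}/Z}; the function nevertheless solves the
#' linear system from the transfer operator itself and checks the residual.
#'
#' @param op a [build_transfer_operator()] result.
#' @param tol acceptable residual \eqn{\lVert \pi T - \pi \rVert_1}.
#' @return numeric probability vector over state indices \code{0..2^n - 1}.
#' @export
stationary_distribution <- function(op, tol = 1e-10) {
  stopifnot(inherits(op, "transfer_operator"))
  m <- op$space$n_states
  if (m == 1) return(1)
  # (T' - I) pi = 0 with the last equation replaced by sum(pi) = 1
  a <- Matrix::t(op$matrix) - Matrix::Diagonal(m)
  a[m, ] <- 1
  b <- c(rep(0, m - 1), 1)
  pi_hat <- as.numeric(Matrix::solve(a, b))
  pi_hat[pi_hat < 0 & pi_hat > -1e-14] <- 0
  pi_hat <- pi_hat / sum(pi_hat)
  residual <- sum(abs(as.numeric(pi_hat %*% op$matrix) - pi_hat))
  if (residual > tol) {
    stop(sprintf("stationary solve did not converge: residual %.3e > %.1e",
                 residual, tol), call. = FALSE)
  }
  pi_hat
}

#' Free-energy profile over the magnetisation coordinate
#'
#' Projects a state distribution onto the macrostate
#' \eqn{\gamma = \langle S \rangle} and reports
#' \eqn{F(\gamma) = -\log \sum_{S : \langle S \rangle = \gamma} \pi(S)}.
#' In the bistable regime the profile has minima at the two attractors
#' (\eqn{\gamma = 0} and \eqn{\gamma = 1}) separated by a barrier whose top —
#' the tipping point — sits at \eqn{\gamma = 0.5}.
#'
#' @param pi probability vector over state indices.
#' @param space the matching [state_space()].
#' @return a data.frame with columns \code{gamma} and \code{free_energy}
#'   (natural-log units).
#' @export
free_energy_profile <- function(pi, space) {
  stopifnot(inherits(space, "state_space"))
  if (length(pi) != space$n_states) {
    stop("`pi` length does not match the state space", call. = FALSE)
  }
  mass <- vapply(0:space$n, function(k) sum(pi[space$ones == k]), numeric(1))
  data.frame(gamma = (0:space$n) / space$n, free_energy = -log(mass))
}

#' Condition a state distribution on a magnetisation level
#'
#' Restricts \code{pi} to the partition cell
#' \eqn{S_\gamma = \{S : \langle S \rangle = \gamma\}} and renormalises.
#' This is the time-0 ensemble used by the information-flow computations:
#' states are grouped by their distance to the tipping point, and within a
#' group they are weighted by the stationary measure.
#'
#' @param pi probability vector over state indices.
#' @param space the matching [state_space()].
#' @param gamma magnetisation level; \code{gamma * n} must be an integer.
#' @return an object of class \code{partition_level}: list with \code{gamma},
#'   \code{member_states} (0-based indices) and \code{conditional_dist}.
#' @export
conditional_state_distribution <- function(pi, space, gamma) {
  stopifnot(inherits(space, "state_space"))
  members <- level_states(space, gamma)
  mass <- pi[members + 1L]
  total <- sum(mass)
  if (total <= 0) {
    stop(sprintf("no probability mass at gamma = %g", gamma), call. = FALSE)
  }
  structure(
    list(gamma = gamma, member_states = members,
         conditional_dist = mass / total),
    class = "partition_level"
  )
}

#' @export
print.partition_level <- function(x, ...) {
  cat(sprintf("<partition_level> gamma = %g, %d member states\n",
              x$gamma, length(x$member_states)))
  invisible(x)
}

#' Joint distribution of a node's present state and the full future state
#'
#' Starting from the conditional ensemble of a magnetisation level, computes
#' \deqn{p(s_i^0 = a, S^t = s') = \sum_{s \in S_\gamma,\ s_i = a}
#'   p(s \mid \gamma)\, T^t[s, s'],}
#' the joint law of node \code{node}'s state at time 0 and the entire system
#' state \code{t} steps later.
#'
#' @param op a [build_transfer_operator()] result.
#' @param level a [conditional_state_distribution()] result.
#' @param node integer node id in \code{0..n-1}.
#' @param t non-negative integer lag.
#' @return a \code{2 x 2^n} matrix; row \code{a + 1} holds the joint mass for
#'   \eqn{s_i^0 = a}, columns are indexed by the future state.
#' @export
evolve_joint <- function(op, level, node, t) {
  stopifnot(inherits(op, "transfer_operator"), inherits(level, "partition_level"))
  node <- check_node(op$system, node)
  t <- as.integer(t)
  if (t < 0) stop("`t` must be >= 0", call. = FALSE)
  joint <- joint_at_zero(op$space, level, node)
  if (t > 0) {
    for (k in seq_len(t)) joint <- joint %*% op$matrix
  }
  joint <- as.matrix(joint)
  dimnames(joint) <- list(node_state = c("0", "1"), NULL)
  joint
}

# 2 x 2^n joint mass at lag 0: conditional distribution split by the node bit.
joint_at_zero <- function(space, level, node) {
  joint <- matrix(0, nrow = 2, ncol = space$n_states)
  bit <- space$bits[level$member_states + 1L, node + 1L]
  joint[cbind(bit + 1L, level$member_states + 1L)] <- level$conditional_dist
  joint
}
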