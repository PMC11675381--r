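#' Networked binary-spin system with Glauber single-flip dynamics
#'
#' Bundles an undirected simple graph with the inverse temperature \eqn{\beta}
#' and a ferromagnetic coupling constant \eqn{J} into the dynamical model used
#' throughout the package.  Node states are binary, \eqn{s_i \in \{0, 1\}},
#' mapped to physical spins \eqn{\sigma_i = 2 s_i - 1 \in \{-1, +1\}} by the
#' zero-field Ising Hamiltonian
#' \deqn{E(S) = -J \sum_{(i,j) \in \mathrm{edges}} \sigma_i \sigma_j.}
#'
#' Nodes are identified by the integer ids \code{0, ..., n - 1}; fixture
#' generators and file readers produce graphs with these ids as vertex names.
#'
#' @param graph an \code{igraph} undirected, simple, connected graph.
#' @param beta inverse temperature (noise parameter), \eqn{\beta \ge 0};
#'   larger values mean less noise.  Default 0.534, the value at which the
#'   10-node kite fixture is bistable with rare spontaneous transitions.
#' @param coupling pairwise coupling constant \eqn{J > 0} (ferromagnetic).
#'
#' @return an object of class \code{spin_system} with elements \code{graph},
#'   \code{n}, \code{beta}, \code{coupling}, \code{adj} (dense 0/1 adjacency
#'   matrix) and \code{degree}.
#' @examples
#' sys <- spin_system(make_kite(), beta = 0.534)
#' sys
#' @export
spin_system <- function(graph, beta = 0.534, coupling = 1) {
  if (!igraph::is_igraph(graph)) {
    stop("`graph` must be an igraph object", call. = FALSE)
  }
  if (igraph::is_directed(graph)) {
    stop("`graph` must be undirected", call. = FALSE)
  }
  if (!igraph::is_simple(graph)) {
    stop("`graph` must be simple (no loops or multi-edges)", call. = FALSE)
  }
  n <- igraph::vcount(graph)
  if (n < 1) stop("graph must have at least one node", call. = FALSE)
  if (n > 1 && !igraph::is_connected(graph)) {
    stop("`graph` must be connected", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || is.na(beta) || beta < 0) {
    stop("`beta` must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(coupling) || length(coupling) != 1 || coupling <= 0) {
    stop("`coupling` must be a single number > 0", call. = FALSE)
  }
  adj <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE))
  adj[adj != 0] <- 1
  structure(
    list(
      graph = graph,
      n = n,
      beta = beta,
      coupling = coupling,
      adj = adj,
      degree = igraph::degree(graph)
    ),
    class = "spin_system"
  )
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "<spin_system> n = %d nodes, %d edges, beta = %g, J = %g\n",
    x$n, igraph::ecount(x$graph), x$beta, x$coupling
  ))
  invisible(x)
}

check_config <- function(system, config) {
  config <- as.integer(config)
  if (length(config) != system$n) {
    stop(sprintf(
      "configuration has length %d but the system has %d nodes",
      length(config), system$n
    ), call. = FALSE)
  }
  if (!all(config %in% c(0L, 1L))) {
    stop("configuration entries must be 0 or 1", call. = FALSE)
  }
  config
}

check_node <- function(system, node) {
  node <- as.integer(node)
  if (length(node) != 1 || is.na(node) || node < 0 || node >= system$n) {
    stop(sprintf("unknown node id %s (valid ids: 0..%d)",
                 paste(node, collapse = ","), system$n - 1), call. = FALSE)
  }
  node
}

#' Ising energy of a spin configuration
#'
#' Evaluates \eqn{E(S) = -J \sum_{(i,j)} \sigma_i \sigma_j} with
#' \eqn{\sigma_i = 2 s_i - 1}.  Aligned edges contribute \eqn{-J}, anti-aligned
#' edges \eqn{+J}; the all-equal configurations are the two ground states.
#'
#' @param system a [spin_system()].
#' @param config length-\code{n} vector of node states in \code{{0, 1}}.
#' @return the (dimensionless) energy.
#' @examples
#' sys <- spin_system(make_kite())
#' energy(sys, rep(0, 10))   # ground state: -J * #edges = -18
#' @export
energy <- function(system, config) {
  config <- check_config(system, config)
  sigma <- 2 * config - 1
  el <- igraph::as_edgelist(system$graph, names = FALSE)
  -system$coupling * sum(sigma[el[, 1]] * sigma[el[, 2]])
}

#' Glauber flip probability of a single node
#'
#' Probability that node \code{node} flips its state, given the current
#' configuration, under the Boltzmann–Gibbs acceptance rule
#' \deqn{P(s_i \to s_i') = \frac{1}{1 + \exp(-\beta \Delta E)},}
#' where \eqn{\Delta E = E(S) - E(S')} is the energy *released* by the flip:
#' energy-lowering flips have probability above one half.  A node whose
#' neighbourhood field vanishes (isolated node, or balanced neighbours) flips
#' with probability exactly 1/2, as does any node at \eqn{\beta = 0}.
#'
#' @param system a [spin_system()].
#' @param config current configuration (0/1 vector of length \code{n}).
#' @param node integer node id in \code{0..n-1}.
#' @return flip probability in \code{(0, 1)}.
#' @examples
#' sys <- spin_system(make_kite(), beta = 1)
#' flip_probability(sys, rep(0, 10), node = 9)  # tail node, one aligned edge
#' @export
flip_probability <- function(system, config, node) {
  config <- check_config(system, config)
  node <- check_node(system, node)
  sigma <- 2 * config - 1
  field <- sum(system$adj[node + 1L, ] * sigma)
  # Flipping sigma_i changes E by 2*J*sigma_i*field; released energy is minus that.
  delta_e <- -2 * system$coupling * sigma[node + 1L] * field
  1 / (1 + exp(-system$beta * delta_e))
}

#' Macrostate (fraction of nodes in state 1)
#'
#' @param config 0/1 configuration vector.
#' @return \eqn{\langle S \rangle \in [0, 1]}, the magnetisation coordinate on
#'   which the tipping point \eqn{\langle S \rangle = 0.5} is defined.
#' @export
macrostate <- function(config) {
  sum(config == 1) / length(config)
}
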