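#' Conditional mutual-information flow curve of a node
#'
#' Computes \eqn{I(s_i^\tau : S^{\tau + t} \mid \langle S^\tau \rangle =
#' \gamma)} in bits for lags \eqn{t = 0, \dots, \tau_{\max}}: the information
#' a node's current state carries about the entire future system state, given
#' that the system currently sits at magnetisation level \eqn{\gamma}.  The
#' time-0 ensemble is the stationary distribution restricted to the level.
#'
#' The curve starts at the node's conditional entropy (at most 1 bit) and is
#' non-increasing in the lag (data-processing along the Markov chain); any
#' long-lag plateau is the node's asymptotic information.
#'
#' @param op a [build_transfer_operator()] result.
#' @param level a [conditional_state_distribution()] result.
#' @param node integer node id in \code{0..n-1}.
#' @param tau_max maximum lag (default 300 steps).
#' @return an object of class \code{mi_curve}: list with \code{node},
#'   \code{gamma}, \code{lags} (\code{0:tau_max}) and \code{values} (bits).
#' @export
mi_curve <- function(op, level, node, tau_max = 300) {
  stopifnot(inherits(op, "transfer_operator"))
  node <- check_node(op$system, node)
  if (tau_max < 1) stop("`tau_max` must be >= 1", call. = FALSE)
  values <- mi_curves_level(op, level, nodes = node, tau_max = tau_max)[1, ]
  structure(
    list(node = node, gamma = level$gamma, lags = 0:tau_max, values = values),
    class = "mi_curve"
  )
}

#' @export
print.mi_curve <- function(x, ...) {
  cat(sprintf("<mi_curve> node %d, gamma = %g, lags 0..%d, I(0) = %.4f bits\n",
              x$node, x$gamma, max(x$lags), x$values[1]))
  invisible(x)
}

# MI curves for several nodes at one partition level, sharing the lag
# evolution.  Row v1[i, ] tracks the joint mass restricted to s_i^0 = 1; the
# complementary mass is full - v1[i, ].  Returns a length(nodes) x (tau_max+1)
# matrix of MI values in bits.
mi_curves_level <- function(op, level, nodes, tau_max) {
  space <- op$space
  m <- space$n_states
  members <- level$member_states + 1L
  full <- numeric(m)
  full[members] <- level$conditional_dist
  v1 <- matrix(0, nrow = length(nodes), ncol = m)
  for (k in seq_along(nodes)) {
    bit1 <- members[space$bits[members, nodes[k] + 1L] == 1L]
    v1[k, bit1] <- full[bit1]
  }
  p1 <- rowSums(v1)                      # marginal p(s_i^0 = 1), lag-invariant
  out <- matrix(0, nrow = length(nodes), ncol = tau_max + 1)
  state <- rbind(full, v1)
  for (t in 0:tau_max) {
    if (t > 0) state <- as.matrix(state %*% op$matrix)
    ps <- state[1, ]
    for (k in seq_along(nodes)) {
      out[k, t + 1] <- mi_from_split(state[k + 1, ], ps, p1[k])
    }
  }
  out
}

# MI in bits between a binary variable A and a discrete S, given the joint
# mass for A = 1 (j1), the S marginal (ps) and p(A = 1).
mi_from_split <- function(j1, ps, p1) {
  if (p1 <= 0 || p1 >= 1) return(0)
  j0 <- ps - j1
  h_term <- function(j, pa) {
    nz <- j > 0
    sum(j[nz] * log2(j[nz] / (pa * ps[nz])))
  }
  h_term(j1, p1) + h_term(j0, 1 - p1)
}

#' Asymptotic information from the tail of an MI curve
#'
#' Estimates the long-lag plateau \eqn{\omega(s_i) \ge 0} as the mean of the
#' curve over its final \code{tail_fraction} of lags (default the last 20%),
#' clipped below at zero.  A positive plateau signals a separation of time
#' scales — persistent correlations that carry which attractor the system is
#' heading to — and rises as the system approaches the tipping point.
#'
#' @param curve an [mi_curve()] or a bare numeric vector of MI values.
#' @param tail_fraction fraction of trailing lags to average, in (0, 0.5].
#' @return \eqn{\omega} in bits.
#' @export
estimate_omega <- function(curve, tail_fraction = 0.2) {
  values <- if (inherits(curve, "mi_curve")) curve$values else as.numeric(curve)
  if (length(values) < 10) {
    stop("MI curve too short to estimate a tail plateau (need >= 10 lags)",
         call. = FALSE)
  }
  if (tail_fraction <= 0 || tail_fraction > 0.5) {
    stop("`tail_fraction` must lie in (0, 0.5]", call. = FALSE)
  }
  n_tail <- max(1L, floor(tail_fraction * length(values)))
  max(0, mean(utils::tail(values, n_tail)))
}

#' Integrated mutual information of a node
#'
#' Sums the excess of the MI curve above the asymptotic plateau,
#' \deqn{\mu = \sum_{t = 0}^{\tau_{\max}} (I(t) - \omega)\, \Delta t,}
#' with \eqn{\Delta t = 1}: the intensity-times-duration of the node's
#' short-lived ("working memory") contribution to the system trajectory.  The
#' infinite upper limit of the defining sum is truncated at the curve horizon.
#'
#' @param curve an [mi_curve()] or numeric vector of MI values (bits).
#' @param omega asymptotic information to subtract (bits), \code{>= 0}.
#' @return \eqn{\mu} in bit-steps.
#' @export
integrated_mi <- function(curve, omega) {
  values <- if (inherits(curve, "mi_curve")) curve$values else as.numeric(curve)
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0) {
    stop("`omega` must be a single number >= 0", call. = FALSE)
  }
  sum(values - omega)
}

#' Full information-flow analysis of a spin system
#'
#' Runs the exact pipeline: for every node and every magnetisation level up to
#' the tipping point, the conditional MI flow curve, the asymptotic
#' information \eqn{\omega}, the integrated mutual information \eqn{\mu}, the
#' max-normalised variants \eqn{\mu^*, \omega^* \in [0, 1]} and the node role
#' score \eqn{r_i = \max_\gamma \mu^*(s_i \mid \gamma) - \max_\gamma
#' \omega^*(s_i) \in [-1, 1]}, the max running over levels strictly below the
#' tipping point (the role contrasts behaviour on the approach; at the
#' tipping level itself every node's curve decays slowly and the integrated
#' term would swamp the contrast).
#'
#' Two \eqn{\omega} conventions are provided.  With \code{omega_mode =
#' "per-level"} (default) each level's curve is integrated above its own tail
#' plateau, so \eqn{\mu} is the transient area under the curve at that level;
#' this is the convention under which low-degree nodes dominate \eqn{\mu} far
#' from the tipping point.  With \code{"shared"} a single \eqn{\omega_i} per
#' node — the largest plateau across levels — is subtracted everywhere.
#'
#' @param system a [spin_system()].
#' @param tau_max lag horizon (default 300).
#' @param levels magnetisation levels to analyse; default all attainable
#'   levels \eqn{\gamma \le 0.5} (results at \eqn{\gamma} and \eqn{1 - \gamma}
#'   coincide by global spin-flip symmetry).
#' @param tail_fraction tail window for [estimate_omega()].
#' @param omega_mode \code{"shared"} or \code{"per-level"}.
#' @param op optionally, a prebuilt [build_transfer_operator()] for
#'   \code{system}.
#' @param keep_curves keep the raw MI curves (a nodes × levels × lags array)?
#' @return an object of class \code{info_flow}: list with matrices \code{mu}
#'   and \code{omega_by_level} (nodes × levels), vectors \code{omega},
#'   \code{mu_star_max}, \code{omega_star}, \code{role_score},
#'   \code{role_label}, the normalised \code{mu_star} matrix, \code{levels},
#'   \code{tau_max}, and (optionally) \code{curves}.
#' @examples
#' \donttest{
#' flows <- info_flow(spin_system(make_kite(), beta = 0.534), tau_max = 300)
#' node_roles(flows)
#' }
#' @export
info_flow <- function(system, tau_max = 300, levels = NULL,
                      tail_fraction = 0.2,
                      omega_mode = c("per-level", "shared"),
                      op = NULL, keep_curves = TRUE) {
  stopifnot(inherits(system, "spin_system"))
  omega_mode <- match.arg(omega_mode)
  if (is.null(op)) op <- build_transfer_operator(system)
  space <- op$space
  if (is.null(levels)) {
    levels <- gamma_levels(space)
    levels <- levels[levels <= 0.5 + 1e-12]
  }
  pi_hat <- stationary_distribution(op)
  nodes <- 0:(system$n - 1)
  n_lev <- length(levels)
  curves <- array(0, dim = c(system$n, n_lev, tau_max + 1),
                  dimnames = list(node = nodes, gamma = signif(levels, 6),
                                  lag = 0:tau_max))
  for (j in seq_len(n_lev)) {
    lev <- conditional_state_distribution(pi_hat, space, levels[j])
    curves[, j, ] <- mi_curves_level(op, lev, nodes, tau_max)
  }
  omega_by_level <- apply(curves, c(1, 2), estimate_omega,
                          tail_fraction = tail_fraction)
  omega_shared <- apply(omega_by_level, 1, max)
  omega_used <- if (omega_mode == "shared") {
    matrix(omega_shared, nrow = system$n, ncol = n_lev)
  } else {
    omega_by_level
  }
  mu <- matrix(0, nrow = system$n, ncol = n_lev,
               dimnames = list(node = nodes, gamma = signif(levels, 6)))
  for (j in seq_len(n_lev)) {
    for (i in seq_len(system$n)) {
      mu[i, j] <- integrated_mi(curves[i, j, ], omega_used[i, j])
    }
  }
  res <- structure(
    list(
      mu = mu,
      omega_by_level = omega_by_level,
      omega = omega_shared,
      levels = levels,
      tau_max = tau_max,
      tail_fraction = tail_fraction,
      omega_mode = omega_mode,
      nodes = nodes,
      degree = system$degree
    ),
    class = "info_flow"
  )
  if (keep_curves) res$curves <- curves
  res <- append_roles(res)
  res
}

# Max-normalisation and the role statistic r_i.  The role contrasts a node's
# behaviour on the approach to the tipping point, so the max over levels runs
# over gamma strictly below 0.5: at the tipping level itself every node's MI
# curve decays slowly (the system is choosing its attractor) and the
# integrated term would swamp the contrast.
append_roles <- function(res) {
  below <- res$levels < 0.5 - 1e-12
  if (!any(below)) below <- rep(TRUE, length(res$levels))
  mu_b <- res$mu[, below, drop = FALSE]
  om_b <- res$omega_by_level[, below, drop = FALSE]
  mu_max <- max(mu_b)
  om_node <- apply(om_b, 1, max)
  om_max <- max(om_node)
  if (mu_max <= 0 || om_max <= 0) {
    stop(paste0("degenerate normalisation: integrated and asymptotic ",
                "information are all zero; roles are undefined"), call. = FALSE)
  }
  res$mu_star <- mu_b / mu_max
  res$omega_star <- om_node / om_max
  res$mu_star_max <- apply(res$mu_star, 1, max)
  score <- res$mu_star_max - res$omega_star
  res$role_score <- pmin(1, pmax(-1, score))
  res$role_label <- ifelse(res$role_score > 0, "initiator",
                           ifelse(res$role_score < 0, "stabilizer", "neutral"))
  res
}

#' @export
print.info_flow <- function(x, ...) {
  cat(sprintf(
    "<info_flow> %d nodes, %d gamma levels, tau_max = %d, omega mode = %s\n",
    length(x$nodes), length(x$levels), x$tau_max, x$omega_mode))
  print(node_roles(x))
  invisible(x)
}

#' Node role table from an information-flow analysis
#'
#' Initiators (role score near +1) inject and propagate short-lived
#' fluctuations that destabilise their neighbours; stabilizers (near -1)
#' carry the long-term memory of which attractor the system settles into.
#'
#' @param flows an [info_flow()] result.
#' @return a data.frame with one row per node: \code{node}, \code{degree},
#'   \code{mu_star_max}, \code{omega_star}, \code{role_score},
#'   \code{role_label}.
#' @export
node_roles <- function(flows) {
  stopifnot(inherits(flows, "info_flow"))
  data.frame(
    node = flows$nodes,
    degree = as.integer(flows$degree),
    mu_star_max = flows$mu_star_max,
    omega_star = flows$omega_star,
    role_score = flows$role_score,
    role_label = flows$role_label,
    row.names = NULL
  )
}

#' Tidy MI-curve table
#'
#' @param flows an [info_flow()] result computed with \code{keep_curves = TRUE}.
#' @return a long data.frame with columns \code{node}, \code{gamma},
#'   \code{lag}, \code{mi} (bits).
#' @export
mi_curve_table <- function(flows) {
  stopifnot(inherits(flows, "info_flow"))
  if (is.null(flows$curves)) {
    stop("curves were not kept; rerun info_flow(keep_curves = TRUE)",
         call. = FALSE)
  }
  d <- dim(flows$curves)
  data.frame(
    node = rep(flows$nodes, times = d[2] * d[3]),
    gamma = rep(rep(flows$levels, each = d[1]), times = d[3]),
    lag = rep(0:(d[3] - 1), each = d[1] * d[2]),
    mi = as.vector(flows$curves)
  )
}
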