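#' Enumerated state space of a binary-spin system
#'
#' Bijectively maps the \eqn{2^n} configurations of an \code{n}-node system to
#' the integer indices \code{0..2^n - 1}.  The encoding is little-endian:
#' node \code{i} contributes bit \code{i}, so the all-zero configuration is
#' index 0 and the all-one configuration is index \eqn{2^n - 1}.  This
#' convention is fixed so that state-indexed outputs are reproducible.
#'
#' @param n number of nodes (capped by default at 14; the state space grows as
#'   \eqn{2^n}).
#' @param cap maximum admissible \code{n}; exceeding it raises a capacity
#'   error pointing at the Monte Carlo simulator.
#' @return an object of class \code{state_space} with elements \code{n},
#'   \code{n_states}, \code{bits} (a \code{2^n x n} 0/1 matrix whose row
#'   \code{k + 1} is the configuration of state \code{k}) and \code{ones}
#'   (number of 1-nodes per state).
#' @export
state_space <- function(n, cap = 14) {
  n <- as.integer(n)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (n > cap) {
    stop(sprintf(paste0(
      "state space for n = %d exceeds the exact-computation cap (n <= %d, ",
      "2^n states); use the Monte Carlo simulator `simulate_glauber()` instead"
    ), n, cap), call. = FALSE)
  }
  n_states <- 2L^n
  idx <- 0:(n_states - 1)
  bits <- vapply(0:(n - 1), function(b) bitwAnd(bitwShiftR(idx, b), 1L),
                 integer(n_states))
  bits <- matrix(bits, nrow = n_states, ncol = n)
  structure(
    list(n = n, n_states = n_states, bits = bits, ones = rowSums(bits)),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> n = %d nodes, %d states (little-endian bits)\n",
              x$n, x$n_states))
  invisible(x)
}

#' Encode a configuration as a state index
#'
#' @param space a [state_space()].
#' @param config 0/1 vector of length \code{n}.
#' @return integer index in \code{0..2^n - 1}.
#' @export
encode_state <- function(space, config) {
  config <- as.integer(config)
  if (length(config) != space$n || !all(config %in% c(0L, 1L))) {
    stop("`config` must be a 0/1 vector of length n", call. = FALSE)
  }
  sum(config * 2L^(0:(space$n - 1)))
}

#' Decode a state index into a configuration
#'
#' @param space a [state_space()].
#' @param index integer index in \code{0..2^n - 1}.
#' @return 0/1 vector of length \code{n}.
#' @export
decode_state <- function(space, index) {
  index <- as.integer(index)
  if (index < 0 || index >= space$n_states) {
    stop("state index out of range", call. = FALSE)
  }
  space$bits[index + 1L, ]
}

#' Magnetisation levels of a state space
#'
#' @param space a [state_space()].
#' @return the attainable macrostate levels \eqn{\gamma \in \{0, 1/n, ..., 1\}}.
#' @export
gamma_levels <- function(space) {
  (0:space$n) / space$n
}

# States (0-based indices) at magnetisation level gamma.
level_states <- function(space, gamma) {
  k <- gamma * space$n
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("gamma = %g is not attainable with n = %d nodes",
                 gamma, space$n), call. = FALSE)
  }
  which(space$ones == round(k)) - 1L
}
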