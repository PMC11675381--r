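# Brute-force oracles, written independently of the package internals:
# explicit loops over edges, states and paths, no shared code with R/.

# configuration of state k (little-endian bits), as plain arithmetic
oracle_config <- function(k, n) {
  vapply(0:(n - 1), function(b) (k %/% 2^b) %% 2, numeric(1))
}

oracle_energy <- function(graph, config, coupling = 1) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  sigma <- 2 * config - 1
  e <- 0
  for (r in seq_len(nrow(el))) {
    e <- e - coupling * sigma[el[r, 1]] * sigma[el[r, 2]]
  }
  e
}

# flip probability from the energy difference of full configurations
oracle_flip_prob <- function(graph, config, node, beta, coupling = 1) {
  flipped <- config
  flipped[node + 1] <- 1 - flipped[node + 1]
  de <- oracle_energy(graph, config, coupling) -
    oracle_energy(graph, flipped, coupling)
  1 / (1 + exp(-beta * de))
}

# dense one-step transition matrix, one entry at a time
oracle_transfer <- function(graph, beta, coupling = 1) {
  n <- igraph::vcount(graph)
  m <- 2^n
  tm <- matrix(0, m, m)
  for (k in 0:(m - 1)) {
    cfg <- oracle_config(k, n)
    for (i in 0:(n - 1)) {
      kk <- k + (1 - 2 * cfg[i + 1]) * 2^i   # index with bit i flipped
      tm[k + 1, kk + 1] <- oracle_flip_prob(graph, cfg, i, beta, coupling) / n
    }
    tm[k + 1, k + 1] <- 1 - sum(tm[k + 1, ])
  }
  tm
}

oracle_boltzmann <- function(graph, beta, coupling = 1) {
  n <- igraph::vcount(graph)
  w <- vapply(0:(2^n - 1), function(k) {
    exp(-beta * oracle_energy(graph, oracle_config(k, n), coupling))
  }, numeric(1))
  w / sum(w)
}

# joint p(s_node^0 = a, S^t = s' | <S^0> = gamma) by literal enumeration of
# every length-t path, starting from the Boltzmann measure restricted to the
# gamma level
oracle_joint <- function(graph, beta, gamma, node, t, coupling = 1) {
  n <- igraph::vcount(graph)
  m <- 2^n
  tm <- oracle_transfer(graph, beta, coupling)
  pi0 <- oracle_boltzmann(graph, beta, coupling)
  ones <- vapply(0:(m - 1), function(k) sum(oracle_config(k, n)), numeric(1))
  lev <- which(abs(ones / n - gamma) < 1e-9)
  w0 <- pi0[lev] / sum(pi0[lev])
  joint <- matrix(0, 2, m)
  for (s0i in seq_along(lev)) {
    s0 <- lev[s0i]
    a <- oracle_config(s0 - 1, n)[node + 1]
    # sum over all paths s0 -> ... -> st of length t
    paths_to <- function(cur, depth) {
      if (depth == 0) {
        v <- numeric(m); v[cur] <- 1
        return(v)
      }
      out <- numeric(m)
      for (nxt in 1:m) {
        if (tm[cur, nxt] > 0) {
          out <- out + tm[cur, nxt] * paths_to(nxt, depth - 1)
        }
      }
      out
    }
    joint[a + 1, ] <- joint[a + 1, ] + w0[s0i] * paths_to(s0, t)
  }
  joint
}

oracle_mi_bits <- function(joint) {
  pa <- rowSums(joint)
  ps <- colSums(joint)
  s <- 0
  for (a in 1:2) for (k in seq_along(ps)) {
    if (joint[a, k] > 0) {
      s <- s + joint[a, k] * log2(joint[a, k] / (pa[a] * ps[k]))
    }
  }
  s
}
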