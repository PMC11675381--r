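triangle <- igraph::make_full_graph(3)

test_that("state encoding is a little-endian bijection", {
  sp <- state_space(4)
  for (k in 0:15) expect_equal(encode_state(sp, decode_state(sp, k)), k)
  expect_equal(decode_state(sp, 1), c(1, 0, 0, 0))     # bit 0 = node 0
  expect_equal(decode_state(sp, 8), c(0, 0, 0, 1))
  expect_error(state_space(15), "cap")
  expect_error(state_space(20, cap = 14), "Monte Carlo")
})

test_that("transfer operator has the single-flip structure and exact rows", {
  # n = 1: both entries 0.5 regardless of beta
  lone <- igraph::make_empty_graph(1, directed = FALSE)
  op1 <- build_transfer_operator(spin_system(lone, beta = 5))
  expect_equal(as.matrix(op1$matrix), matrix(0.5, 2, 2), ignore_attr = TRUE)

  # beta = 0: every single-flip entry 1/(2n), diagonal 1/2
  sys0 <- spin_system(make_kite(), beta = 0)
  op0 <- build_transfer_operator(sys0)
  tm0 <- op0$matrix
  expect_equal(unname(Matrix::diag(tm0)), rep(0.5, 1024))
  off <- Matrix::drop0(tm0 - Matrix::Diagonal(1024, Matrix::diag(tm0)))
  expect_equal(unique(round(off@x, 12)), 1 / 20)

  # triangle at beta = 1: entrywise agreement with the brute-force oracle
  sys <- spin_system(triangle, beta = 1)
  op <- build_transfer_operator(sys)
  expect_equal(as.matrix(op$matrix), oracle_transfer(triangle, 1),
               tolerance = 1e-12, ignore_attr = TRUE)

  # rows sum to one; off-diagonal support only at Hamming distance 1
  expect_equal(unname(Matrix::rowSums(op$matrix)), rep(1, 8), tolerance = 1e-12)
  dense <- as.matrix(op$matrix)
  for (s in 0:7) for (sp in 0:7) {
    hd <- sum(oracle_config(s, 3) != oracle_config(sp, 3))
    if (hd > 1) expect_identical(dense[s + 1, sp + 1], 0)
  }
})

test_that("powers of the transfer operator stay row-stochastic", {
  op <- kite_op()
  tm <- op$matrix
  for (t in c(1, 10, 100)) {
    tt <- tm
    k <- 1
    while (k < t) { tt <- tt %*% tm; k <- k + 1 }
    expect_lt(max(abs(Matrix::rowSums(tt) - 1)), 1e-10)
    if (t == 100) break
  }
})

test_that("stationary distribution solves pi T = pi and matches Boltzmann", {
  # beta = 0: uniform
  op0 <- build_transfer_operator(spin_system(triangle, beta = 0))
  expect_equal(stationary_distribution(op0), rep(1 / 8, 8), tolerance = 1e-10)

  # triangle at beta = 1: Boltzmann weights (detailed balance of Glauber)
  op <- build_transfer_operator(spin_system(triangle, beta = 1))
  pi_hat <- stationary_distribution(op)
  expect_equal(pi_hat, oracle_boltzmann(triangle, 1), tolerance = 1e-10)

  # kite: global-flip symmetry pi(S) = pi(complement of S)
  opk <- kite_op()
  pik <- stationary_distribution(opk)
  expect_equal(pik, rev(pik), tolerance = 1e-10)
})

test_that("Glauber dynamics satisfies detailed balance w.r.t. pi", {
  op <- kite_op()
  pi_hat <- stationary_distribution(op)
  tm <- op$matrix
  idx <- 0:1023
  for (b in 0:9) {
    j <- bitwXor(idx, 2L^b)
    fwd <- pi_hat * tm[cbind(idx + 1L, j + 1L)]
    bwd <- pi_hat[j + 1L] * tm[cbind(j + 1L, idx + 1L)]
    expect_lt(max(abs(fwd - bwd)), 1e-10)
  }
})

test_that("free-energy profile is binomial at beta = 0 and symmetric", {
  sp <- state_space(10)
  op0 <- build_transfer_operator(spin_system(make_kite(), beta = 0))
  prof0 <- free_energy_profile(stationary_distribution(op0), sp)
  expect_equal(prof0$free_energy, -log(choose(10, 0:10) / 2^10),
               tolerance = 1e-8)
  # single interior minimum at gamma = 0.5 when noise dominates
  expect_equal(which.min(prof0$free_energy), 6)

  prof <- free_energy_profile(stationary_distribution(kite_op()), sp)
  expect_equal(prof$free_energy, rev(prof$free_energy), tolerance = 1e-10)
})

test_that("conditional level distributions restrict and renormalise pi", {
  sp <- state_space(10)
  pik <- stationary_distribution(kite_op())
  lev0 <- conditional_state_distribution(pik, sp, 0)
  expect_equal(lev0$member_states, 0L)
  expect_equal(lev0$conditional_dist, 1)

  # beta = 0: uniform within each level
  op0 <- build_transfer_operator(spin_system(make_kite(), beta = 0))
  lev <- conditional_state_distribution(stationary_distribution(op0), sp, 0.3)
  expect_equal(length(lev$member_states), choose(10, 3))
  expect_equal(lev$conditional_dist, rep(1 / choose(10, 3), choose(10, 3)))

  # kite level gamma = 0.1: ten states, Boltzmann-restricted weights
  lev1 <- conditional_state_distribution(pik, sp, 0.1)
  expect_equal(length(lev1$member_states), 10)
  bw <- oracle_boltzmann(make_kite(), 0.534)
  w <- bw[lev1$member_states + 1]
  expect_equal(lev1$conditional_dist, w / sum(w), tolerance = 1e-9)

  expect_error(conditional_state_distribution(pik, sp, 0.15), "attainable")
})

test_that("evolve_joint reproduces path enumeration and conserves mass", {
  sys <- spin_system(triangle, beta = 1)
  op <- build_transfer_operator(sys)
  pi_hat <- stationary_distribution(op)
  lev <- conditional_state_distribution(pi_hat, op$space, 1 / 3)

  # t = 0: the full state determines the node state (block-diagonal joint)
  j0 <- evolve_joint(op, lev, 0, 0)
  expect_equal(sum(j0), 1, tolerance = 1e-12)
  for (k in lev$member_states) {
    a <- op$space$bits[k + 1, 1]
    expect_equal(unname(j0[2 - a, k + 1]), 0)
  }

  # t = 2: literal sum over every length-2 path
  for (nd in 0:2) {
    j2 <- evolve_joint(op, lev, nd, 2)
    expect_equal(unname(j2), oracle_joint(triangle, 1, 1 / 3, nd, 2),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(sum(j2), 1, tolerance = 1e-12)
    # marginal over the node state is lag-invariant
    expect_equal(rowSums(j2), rowSums(j0 <- evolve_joint(op, lev, nd, 0)),
                 tolerance = 1e-12)
  }

  # isolated single node, one step: joint factorises (memoryless coin)
  lone <- igraph::make_empty_graph(1, directed = FALSE)
  opl <- build_transfer_operator(spin_system(lone, beta = 2))
  pil <- stationary_distribution(opl)
  levl <- conditional_state_distribution(pil, opl$space, 0.5 * 0 + 0)  # gamma 0
  j1 <- evolve_joint(opl, levl, 0, 1)
  expect_equal(unname(j1), rbind(c(0.5, 0.5), c(0, 0)), ignore_attr = TRUE)
})
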