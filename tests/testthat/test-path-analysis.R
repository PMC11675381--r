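triangle <- igraph::make_full_graph(3)

test_that("trajectory counts are purely combinatorial", {
  op3 <- build_transfer_operator(spin_system(triangle, beta = 1))
  # one step: one trajectory per node
  tr1 <- enumerate_tipping_trajectories(op3, c(0, 0, 0), 1, 1 / 3)
  expect_equal(nrow(tr1$states), 3)
  # two steps to gamma = 2/3: ordered flip pairs, 3 * 2
  tr2 <- enumerate_tipping_trajectories(op3, c(0, 0, 0), 2, 2 / 3)
  expect_equal(nrow(tr2$states), 6)
  # unreachable target: empty set, not an error
  tr0 <- enumerate_tipping_trajectories(op3, c(0, 0, 0), 1, 1)
  expect_equal(nrow(tr0$states), 0)

  # kite, five flips in five steps: n (n-1) ... (n-4)
  trk <- enumerate_tipping_trajectories(kite_op(), rep(0, 10), 5, 0.5)
  expect_equal(nrow(trk$states), 10 * 9 * 8 * 7 * 6)
  # the count does not depend on beta
  trk0 <- enumerate_tipping_trajectories(
    build_transfer_operator(spin_system(make_kite(), beta = 0)),
    rep(0, 10), 5, 0.5)
  expect_equal(nrow(trk0$states), nrow(trk$states))
})

test_that("trajectory objectives are reproducible from transfer entries", {
  op <- kite_op()
  tr <- enumerate_tipping_trajectories(op, rep(0, 10), 5, 0.5)
  expect_equal(tr$objective, rowSums(tr$step_logps), tolerance = 1e-12)
  set.seed(3)
  dense_lookup <- function(i, j) op$matrix[i, j]
  for (r in sample(nrow(tr$states), 25)) {
    lp <- vapply(1:5, function(t)
      log(dense_lookup(tr$states[r, t] + 1, tr$states[r, t + 1] + 1)),
      numeric(1))
    expect_equal(tr$step_logps[r, ], lp, tolerance = 1e-12)
  }
  # consecutive states differ in exactly one node
  hams <- abs(op$space$bits[tr$states[, 1] + 1, ] -
                op$space$bits[tr$states[, 2] + 1, ])
  expect_true(all(rowSums(hams) == 1))
})

test_that("stay-steps are admitted only when requested", {
  op3 <- build_transfer_operator(spin_system(triangle, beta = 1))
  # 3 steps to gamma = 1/3 with stays: flip+stay+stay interleavings and
  # flip-flip-flip paths; without stays, only parity-compatible flip paths
  no_stay <- enumerate_tipping_trajectories(op3, c(0, 0, 0), 3, 1 / 3)
  with_stay <- enumerate_tipping_trajectories(op3, c(0, 0, 0), 3, 1 / 3,
                                              allow_stays = TRUE)
  expect_gt(nrow(with_stay$states), nrow(no_stay$states))
  expect_equal(with_stay$objective, rowSums(with_stay$step_logps),
               tolerance = 1e-12)
})

test_that("maximal trajectories form an exact tie class", {
  # beta = 0: every trajectory ties at 5 * log(1/(2n))
  op0 <- build_transfer_operator(spin_system(make_kite(), beta = 0))
  tr0 <- enumerate_tipping_trajectories(op0, rep(0, 10), 5, 0.5)
  mx0 <- maximal_trajectories(tr0)
  expect_equal(nrow(mx0$states), 30240)
  expect_equal(mx0$objective[1], 5 * log(1 / 20), tolerance = 1e-12)

  # unique maximum: singleton
  fake <- tr0
  fake$objective[7] <- 1
  expect_equal(nrow(maximal_trajectories(fake)$states), 1)

  expect_error(maximal_trajectories(
    spinflow:::empty_trajectory_set(0L, 5, 0.5)), "empty")
})

test_that("kite maximizers start from the tail and respect the mirror symmetry", {
  op <- kite_op()
  tr <- enumerate_tipping_trajectories(op, rep(0, 10), 5, 0.5)
  mx <- maximal_trajectories(tr)
  expect_gt(nrow(mx$states), 1)
  # every maximizer's flip set includes tail nodes 9, 8, 7 and its first
  # flips are low-degree: the cascade runs tail to core
  first_flip <- log2(bitwXor(mx$states[, 1], mx$states[, 2]))
  expect_true(all(first_flip %in% c(2, 4, 9)))
  final_bits <- op$space$bits[mx$states[, 6] + 1, , drop = FALSE]
  expect_true(all(final_bits[, 8 + 1] == 1 & final_bits[, 9 + 1] == 1))

  # closure under the mirror automorphism (0<->1, 2<->4, 5<->6)
  mirror_state <- function(s) {
    bits <- op$space$bits[s + 1, ]
    encode_state(op$space, bits[kite_mirror + 1])
  }
  mirrored <- apply(mx$states, c(1, 2), mirror_state)
  key <- function(m) apply(m, 1, paste, collapse = "-")
  expect_setequal(key(mirrored), key(mx$states))
})

test_that("commitment probabilities match a brute-force two-node check", {
  edge <- igraph::make_graph(~ a - b)
  sys <- spin_system(edge, beta = 0.7)
  op <- build_transfer_operator(sys)
  got <- commitment_probabilities(op, 0, horizon = 1)

  # oracle: Boltzmann restricted to gamma = 0.5 -> one step of the exact T
  tm <- oracle_transfer(edge, 0.7)
  pi0 <- oracle_boltzmann(edge, 0.7)
  lev <- c(2, 3)  # states 01, 10 (1-based indices of indices 1 and 2)
  w <- pi0[lev] / sum(pi0[lev])
  ones <- c(0, 1, 1, 2)
  for (a in 0:1) {
    # node 0 state a at the tipping level: state index 1 has node0 = 1
    s0 <- if (a == 1) 2 else 3
    dist1 <- tm[s0, ]
    expect_equal(got$p_above[a + 1], sum(dist1[ones > 1]), tolerance = 1e-12)
    expect_equal(got$p_below[a + 1], sum(dist1[ones < 1]), tolerance = 1e-12)
    expect_equal(got$p_tie[a + 1], sum(dist1[ones == 1]), tolerance = 1e-12)
  }

  # beta = 0: the node state carries no commitment information
  op0 <- build_transfer_operator(spin_system(edge, beta = 0))
  got0 <- commitment_probabilities(op0, 0, horizon = 3)
  expect_equal(got0$p_above[1], got0$p_above[2], tolerance = 1e-12)
  expect_equal(got0$p_agree[1], got0$p_agree[2], tolerance = 1e-12)

  expect_error(commitment_probabilities(
    build_transfer_operator(spin_system(triangle, beta = 1)), 0, 10), "odd")
})

test_that("hub and tail-side nodes commit in opposite directions on the kite", {
  op <- kite_op()
  c3 <- commitment_probabilities(op, 3, horizon = 10)
  c8 <- commitment_probabilities(op, 8, horizon = 10)
  # node 3 agrees in sign with the future macrostate, node 8 disagrees
  agree_frac <- function(cp, a) {
    # agreement probability renormalised over decided outcomes
    decided <- cp$p_above[a + 1] + cp$p_below[a + 1]
    cp$p_agree[a + 1] / decided
  }
  expect_gt(agree_frac(c3, 1), 0.5)
  expect_gt(agree_frac(c3, 0), 0.5)
  expect_lt(agree_frac(c8, 1), 0.5)
  expect_lt(agree_frac(c8, 0), 0.5)
})

test_that("trajectory tables decode states per step", {
  op <- kite_op()
  tr <- enumerate_tipping_trajectories(op, rep(0, 10), 5, 0.5)
  mx <- maximal_trajectories(tr)
  tab <- trajectory_table(mx, op$space, which = 1)
  expect_equal(nrow(tab), 6 * 10)
  expect_equal(sum(tab$state[tab$step == 0]), 0)
  expect_equal(sum(tab$state[tab$step == 5]), 5)
})
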