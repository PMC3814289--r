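# Exact stochastic simulation and stationary moment estimation.

test_that("a pure death process counts down and absorbs", {
  net <- reaction_network(
    data.frame(id = "X", initial = 0.3),
    list(reaction("death", c(X = 1), NULL, mass_action("d"))),
    parameters = c(d = 1), system_size = 10)   # n0 = 3
  tr <- gillespie_direct(net, t_end = 1000, seed = 1)
  expect_equal(tr$n_events, 3)
  expect_true(tr$absorbed)
  expect_equal(unname(tr$final_state), 0)
  # zero initial state: absorbed immediately, constant trajectory
  tr0 <- gillespie_direct(net, n0 = 0, t_end = 10, seed = 1)
  expect_true(tr0$absorbed)
  expect_equal(tr0$n_events, 0)
  expect_equal(nrow(tr0$states), 1L)
})

test_that("every recorded increment is a stoichiometry column", {
  net <- michaelis_menten(omega = 20)
  tr <- gillespie_direct(net, t_end = 30, seed = 8)
  expect_gt(tr$n_events, 50)
  N <- stoichiometry_matrix(net)
  inc <- diff(tr$states)
  for (r in seq_len(nrow(inc))) {
    match_col <- apply(N, 2, function(cc) all(cc == inc[r, ]))
    expect_true(any(match_col))
  }
  expect_true(all(tr$states >= 0))
  expect_true(all(diff(tr$times) > 0))
})

test_that("the general-kinetics loop obeys the same contract", {
  net <- erk_cascade()   # saturating rate laws: R event loop
  tr <- gillespie_direct(net, t_end = 3, seed = 2)
  expect_gt(tr$n_events, 5)
  N <- stoichiometry_matrix(net)
  inc <- diff(tr$states)
  for (r in seq_len(nrow(inc)))
    expect_true(any(apply(N, 2, function(cc) all(cc == inc[r, ]))))
  expect_true(all(tr$states >= 0))
})

test_that("trajectories are reproducible by seed", {
  a <- gillespie_direct(birth_death(), t_end = 10, seed = 12)
  b <- gillespie_direct(birth_death(), t_end = 10, seed = 12)
  d <- gillespie_direct(birth_death(), t_end = 10, seed = 13)
  expect_identical(a$times, b$times)
  expect_identical(a$states, b$states)
  expect_false(identical(a$times, d$times))
})

test_that("time-weighted moments are exact on a hand-made trajectory", {
  # state 0 held for 1 time unit, then state 2 held for 1 time unit:
  # mean 1, variance 1
  traj <- structure(list(times = c(0, 1), states = matrix(c(0, 2), 2, 1),
                         t_end = 2, t_final = 2, n_events = 1,
                         absorbed = FALSE), class = "ssa_trajectory")
  m <- stationary_moments(traj, burn_in = 0)
  expect_equal(unname(m$mean), 1)
  expect_equal(unname(m$cov[1, 1]), 1)
  expect_equal(m$window, 2)
  expect_error(stationary_moments(traj, burn_in = 2), "burn_in")
})

test_that("the stationary mean matches the analytic value within error", {
  net <- birth_death(k = 5, d = 0.5, omega = 10)   # stationary mean 100
  m <- ssa_moments(net, t_end = 2000, seed = 4)
  expect_lt(abs(m$mean - 100), 3 * m$se_mean + 1e-9)
  # linear network: Fano -> 1 within Monte Carlo error
  fano <- m$cov[1, 1] / m$mean
  expect_lt(abs(fano - 1), 0.1)
})

test_that("block and trajectory estimators agree on the same run", {
  net <- birth_death(omega = 5)
  tr <- gillespie_direct(net, t_end = 500, seed = 6)
  m_tr <- stationary_moments(tr, burn_in = 50)
  m_blk <- ssa_moments(net, t_end = 500, burn_in = 50,
                       n0 = tr$states[1, ], seed = 6)
  expect_equal(unname(m_tr$mean), unname(m_blk$mean), tolerance = 1e-10)
  expect_equal(unname(m_tr$cov), unname(m_blk$cov), tolerance = 1e-9)
})

test_that("LNA and SSA covariances agree on a linear network", {
  cmp <- compare_lna_ssa(birth_death(k = 5, d = 0.5, omega = 10),
                         t_end = 2e4, seed = 1)
  expect_lt(max(abs(cmp$rel_diff)), 0.03)
  # determinism split: the LNA column is seed-independent
  cmp2 <- compare_lna_ssa(birth_death(k = 5, d = 0.5, omega = 10),
                          t_end = 2e4, seed = 99)
  expect_identical(cmp$lna, cmp2$lna)
  expect_false(identical(cmp$ssa, cmp2$ssa))
})

test_that("longer runs shrink the LNA-SSA discrepancy", {
  net <- mm_validation(omega = 50)
  err <- vapply(c(2e3, 3e4), function(tend) {
    ds <- vapply(1:3, function(s) {
      cmp <- compare_lna_ssa(net, t_end = tend, seed = s)
      max(abs(cmp$rel_diff))
    }, 0)
    mean(ds)
  }, 0)
  expect_lt(err[2], err[1])
})
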