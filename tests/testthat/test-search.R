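# Parameter scans and the two global optimisers.

test_that("a 1D scan tabulates the statistic over the grid", {
  sc <- scan_statistic(birth_death(k = 5, d = 0.5, omega = 10), "var(X)",
                       param_range("d", 0.25, 1), points = 7)
  expect_s3_class(sc, "tbl_df")
  expect_equal(nrow(sc), 7L)
  expect_equal(sc$d, seq(0.25, 1, length.out = 7))
  expect_true(all(sc$feasible))
  # var(X) = Omega k / d: strictly decreasing in d
  expect_true(all(diff(sc$value) < 0))
  expect_equal(sc$value, 10 * 5 / sc$d, tolerance = 1e-8)
})

test_that("2D grids are row-major with the first parameter slowest", {
  sc <- scan_statistic(birth_death(), "var(X)",
                       list(param_range("k", 1, 2),
                            param_range("d", 0.5, 1)), points = c(2, 3))
  expect_equal(sc$k, rep(c(1, 2), each = 3))
  expect_equal(sc$d, rep(c(0.5, 0.75, 1), times = 2))
})

test_that("infeasible grid points are flagged, not dropped", {
  sc <- scan_statistic(erk_cascade(), "var(MKKK)",
                       param_range("V2", 0.40, 0.50), points = 5)
  expect_equal(nrow(sc), 5L)
  expect_true(any(sc$feasible) && any(!sc$feasible))
  expect_true(all(is.na(sc$value[!sc$feasible])))
  expect_true(all(!is.na(sc$reason[!sc$feasible])))
})

test_that("particle swarm minimises a smooth bowl", {
  sphere <- function(p) sum((p - 0.3)^2)
  res <- particle_swarm(sphere, rep(-5, 5), rep(5, 5), swarm_size = 50,
                        max_iter = 200, seed = 2, stall_iter = 200)
  expect_lt(res$best_value, 1e-6)
  expect_equal(unname(res$best_parameters), rep(0.3, 5), tolerance = 1e-3)
})

test_that("optimisers are deterministic under a fixed seed", {
  sphere <- function(p) sum(p^2)
  a <- particle_swarm(sphere, -2, 2, swarm_size = 10, max_iter = 30, seed = 7)
  b <- particle_swarm(sphere, -2, 2, swarm_size = 10, max_iter = 30, seed = 7)
  expect_identical(a$trace, b$trace)
  expect_identical(a$best_parameters, b$best_parameters)
  e1 <- evolutionary_programming(sphere, -2, 2, pop_size = 10,
                                 generations = 30, seed = 7)
  e2 <- evolutionary_programming(sphere, -2, 2, pop_size = 10,
                                 generations = 30, seed = 7)
  expect_identical(e1$trace, e2$trace)
})

test_that("every candidate stays inside the declared bounds", {
  seen <- NULL
  watched <- function(p) { seen <<- rbind(seen, p); sum(p^2) }
  particle_swarm(watched, c(-1, 0), c(2, 5), swarm_size = 8, max_iter = 20,
                 seed = 3, stall_iter = 50)
  expect_true(all(seen[, 1] >= -1 & seen[, 1] <= 2))
  expect_true(all(seen[, 2] >= 0 & seen[, 2] <= 5))
  seen <- NULL
  evolutionary_programming(watched, c(-1, 0), c(2, 5), pop_size = 8,
                           generations = 20, seed = 3, stall_iter = 50)
  expect_true(all(seen[, 1] >= -1 & seen[, 1] <= 2))
  expect_true(all(seen[, 2] >= 0 & seen[, 2] <= 5))
})

test_that("best-so-far traces never worsen", {
  rough <- function(p) sum(p^2) + sin(10 * p[1])
  for (res in list(
    particle_swarm(rough, c(-3, -3), c(3, 3), swarm_size = 12,
                   max_iter = 40, seed = 5),
    evolutionary_programming(rough, c(-3, -3), c(3, 3), pop_size = 12,
                             generations = 40, seed = 5))) {
    expect_true(all(diff(res$trace$best) <= 0))
    expect_equal(res$best_value, min(res$trace$best))
  }
})

test_that("evolutionary programming handles optima at the boundary", {
  res <- evolutionary_programming(function(p) (p - 10)^2, 0, 1,
                                  pop_size = 20, generations = 60, seed = 1)
  expect_equal(unname(res$best_parameters), 1, tolerance = 1e-6)
  res2 <- evolutionary_programming(function(p) sum((p - 0.3)^2),
                                   rep(-5, 3), rep(5, 3),
                                   pop_size = 20, generations = 200,
                                   seed = 4, stall_iter = 200)
  expect_lt(res2$best_value, 1e-4)
})

test_that("the closed-loop wrapper reports on the objective scale", {
  net <- birth_death(k = 5, d = 0.5, omega = 10)
  opt <- optimise_noise(net, objective_spec("var(X)", "minimise"),
                        param_range("d", 0.25, 1),
                        method = "particle_swarm", seed = 1,
                        swarm_size = 10, max_iter = 25)
  # var = Omega k / d is minimal at the upper bound d = 1
  expect_equal(unname(opt$best_parameters["d"]), 1, tolerance = 1e-4)
  expect_equal(opt$best_value, 50, tolerance = 1e-3)
  expect_equal(opt$direction, "minimise")
  gl <- glance(opt)
  expect_equal(gl$best_value, opt$best_value)
  expect_true(all(diff(tidy(opt)$best) <= 0))
})
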