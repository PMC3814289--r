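# The LNA engine: drift/diffusion matrices, Lyapunov solve, covariance
# recovery, and the exactness/scaling properties of the approximation.

test_that("drift and diffusion matrices match the analytic forms", {
  # reduced Michaelis-Menten at k = 1, beta = 10, x* = (2/9, 1, 1):
  # hand-evaluated Jacobian and second-jump-moment matrices
  rs <- reduce_network(michaelis_menten())
  ss <- find_steady_state(rs)
  A <- drift_matrix(rs, ss$x_ind)
  B <- diffusion_matrix(rs, ss$x_ind)
  expect_equal(unname(A),
               rbind(c(-9, 2 / 9 + 1, 0),
                     c(9, -2 / 9 - 2, 0),
                     c(0, 1, -1)), tolerance = 1e-8)
  expect_equal(unname(B),
               rbind(c(4, -3, 0),
                     c(-3, 4, -1),
                     c(0, -1, 2)), tolerance = 1e-8)
  # B is PSD
  expect_gte(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
})

test_that("analytic Jacobian agrees with central finite differences", {
  net <- erk_cascade()
  rs <- reduce_network(net)
  ss <- find_steady_state(rs)
  A <- drift_matrix(rs, ss$x_ind)
  h <- 1e-5
  A_fd <- matrix(0, rs$K, rs$K)
  for (j in seq_len(rs$K)) {
    xp <- ss$x_ind; xm <- ss$x_ind
    step <- max(h, h * abs(ss$x_ind[j]))
    xp[j] <- xp[j] + step; xm[j] <- xm[j] - step
    A_fd[, j] <- (lnakit:::drift_reduced(rs, xp) -
                    lnakit:::drift_reduced(rs, xm)) / (2 * step)
  }
  expect_equal(unname(A), A_fd, tolerance = 1e-6)
})

test_that("the Schur solver solves textbook Lyapunov equations", {
  expect_equal(unname(solve_lyapunov(matrix(-1), matrix(2), 1)),
               matrix(1), ignore_attr = TRUE)
  C <- solve_lyapunov(diag(c(-1, -2)), diag(2), omega = 2)
  expect_equal(unname(C), diag(c(1, 0.5)), ignore_attr = TRUE)
  expect_error(solve_lyapunov(diag(c(1, -1)), diag(2)), "not asymptotically")
  expect_error(solve_lyapunov(matrix(c(0, -1, 1, 0), 2), diag(2)),
               "not asymptotically")
})

test_that("Schur-based solve matches the Kronecker oracle", {
  set.seed(42)
  for (i in 1:50) {
    K <- sample(2:6, 1)
    A <- random_stable(K)
    B <- crossprod(matrix(stats::rnorm(K * K), K))
    om <- stats::runif(1, 0.5, 20)
    C1 <- solve_lyapunov(A, B, om)
    C2 <- lyap_kron(A, B, om)
    expect_lt(max(abs(C1 - C2)) / max(abs(C2)), 1e-8)
    # residual invariant holds
    expect_lt(max(abs(A %*% C1 + C1 %*% t(A) + om * B)) /
                max(abs(om * B)), 1e-9)
  }
})

test_that("covariance recovery enforces the conservation structure", {
  res <- lna(michaelis_menten())
  C <- res$C
  expect_equal(C["E", "E"], C["SE", "SE"])
  expect_equal(C["S", "E"], -C["S", "SE"])
  expect_equal(C["P", "E"], -C["P", "SE"])
  # the conserved total does not fluctuate
  g <- c(0, 1, 0, 1)
  expect_lt(abs(t(g) %*% C %*% g), 1e-9 * sum(diag(C)))
  expect_equal(C, t(C))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9 * sum(diag(C)))
  # identity link when nothing is conserved
  res_bd <- lna(birth_death())
  expect_equal(res_bd$C, res_bd$C_red, ignore_attr = TRUE)
})

test_that("conserved totals have zero variance on every fixture", {
  for (net in list(michaelis_menten(), erk_cascade(), cycle_network())) {
    res <- lna(net)
    rs <- res$reduced_system
    for (l in seq_len(rs$Lambda)) {
      g <- rs$moieties[l, ]
      expect_lt(abs(t(g) %*% res$C %*% g), 1e-9 * sum(diag(res$C)))
    }
  }
})

test_that("open monomolecular networks are exactly Poisson", {
  res <- lna(birth_death(k = 5, d = 0.5, omega = 10))
  expect_equal(unname(res$C[1, 1]), unname(res$means[1]), tolerance = 1e-10)
  res3 <- lna(linear_chain(influx = 5, rates = c(1, 2, 0.5), length = 3))
  offdiag <- res3$C - diag(diag(res3$C))
  expect_lt(max(abs(offdiag)), 1e-8 * sum(diag(res3$C)))
  expect_equal(unname(diag(res3$C)), unname(res3$means), tolerance = 1e-8)
})

test_that("particle-number covariance scales linearly with system size", {
  for (make in list(function(om) michaelis_menten(omega = om),
                    function(om) birth_death(omega = om))) {
    C1 <- lna(make(20))$C
    C10 <- lna(make(200))$C
    expect_equal(C10, 10 * C1, tolerance = 1e-8)
  }
})

test_that("the concentration-scale covariance is C_red / Omega", {
  res <- lna(michaelis_menten(omega = 250))
  expect_equal(res$Xi * 250, res$C_red, ignore_attr = TRUE)
})

test_that("near-bifurcation covariances carry a warning", {
  expect_warning(lna(erk_cascade(), params = c(V2 = 0.4455)), "bifurcation")
  expect_silent(invisible(lna(erk_cascade(), params = c(V2 = 0.41))))
})

test_that("tidy and glance summarise an LNA result", {
  res <- lna(michaelis_menten())
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4 * 5 / 2)   # unordered pairs incl. diagonal
  expect_equal(td$fano[td$species_i == "S" & td$species_j == "S"],
               res$C["S", "S"] / res$means["S"], ignore_attr = TRUE)
  gl <- glance(res)
  expect_equal(gl$n_conserved, 1L)
  expect_lt(gl$lyapunov_residual, 1e-9)
})
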