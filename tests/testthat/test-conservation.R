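# Conserved-moiety detection, link matrix, and system reduction.

test_that("Michaelis-Menten has the single enzyme moiety", {
  net <- michaelis_menten()
  rel <- find_conservation_relations(stoichiometry_matrix(net))
  expect_equal(rel$independent, 1:3)      # S, SE, P
  expect_equal(rel$dependent, 4)          # E
  expect_length(rel$relations, 1L)
  r <- rel$relations[[1]]
  expect_equal(r$g, c(0, 1, 0, 1))        # [SE] + [E] conserved
  expect_equal(r$alpha, c(0, -1, 0))      # E = const - SE

  expect_equal(link_matrix(rel), rbind(diag(3), c(0, -1, 0)))

  rs <- reduce_network(net)
  expect_equal(rs$K, 3L)
  expect_equal(rs$Lambda, 1L)
  expect_equal(rs$constants, 10)          # beta from the initial state
  expect_equal(unname(rs$L),
               rbind(diag(3), c(0, -1, 0)), ignore_attr = TRUE)
})

test_that("moiety vectors annihilate the stoichiometry exactly", {
  for (net in list(michaelis_menten(), erk_cascade(), cycle_network(),
                   two_branch_cascade())) {
    N <- stoichiometry_matrix(net)
    rs <- reduce_network(net)
    if (rs$Lambda > 0)
      expect_identical(unname(rs$moieties %*% N),
                       matrix(0, rs$Lambda, ncol(N)))
    expect_equal(qr(rs$N_red)$rank, rs$K)
  }
})

test_that("open networks reduce to the identity", {
  for (net in list(birth_death(), linear_chain())) {
    rs <- reduce_network(net)
    expect_equal(rs$Lambda, 0L)
    expect_equal(unname(rs$L), diag(rs$K))
    expect_equal(rs$independent, seq_len(rs$K))
  }
})

test_that("a closed cycle conserves the total mass", {
  rs <- reduce_network(cycle_network())
  expect_equal(rs$Lambda, 1L)
  expect_equal(rs$moieties[1, ], c(1, 1, 1))  # A + B + C
  expect_equal(unname(rs$L), rbind(diag(2), c(-1, -1)), ignore_attr = TRUE)
})

test_that("the ERK cascade has one moiety per kinase tier", {
  rs <- reduce_network(erk_cascade())
  expect_equal(rs$Khat, 8L)
  expect_equal(rs$Lambda, 3L)
  expect_equal(rs$K, 5L)
  # tier totals at the initial state, in particles
  totals <- rs$moieties %*% (rs$net$species$initial * rs$net$system_size)
  expect_equal(as.numeric(totals),
               c(100, 300, 300) * rs$net$system_size)
})

test_that("reduced dynamics reproduce the full dynamics", {
  net <- michaelis_menten()
  rs <- reduce_network(net)
  set.seed(5)
  for (i in 1:20) {
    xi <- stats::runif(3, 0, 3)
    xi[2] <- min(xi[2], 10)  # keep E = beta - SE non-negative
    expect_equal(lnakit:::drift_reduced(rs, xi),
                 mm_rhs_reduced(xi, beta = 10), tolerance = 1e-12)
    # reduced drift is the independent rows of the full drift
    full <- drift(net, lnakit:::full_state(rs, xi))
    expect_equal(lnakit:::drift_reduced(rs, xi), unname(full[1:3]),
                 tolerance = 1e-12)
  }
})

test_that("full covariance is invariant under the species declaration order", {
  # permuting the declared species changes which ones are retained as
  # independent, but must not change the recovered full covariance
  base <- michaelis_menten()
  C1 <- lna(base)$C
  perm <- c("E", "SE", "S", "P")   # forces a different dependent choice
  net2 <- reaction_network(
    species = base$species[match(perm, base$species$id), ],
    reactions = base$reactions, parameters = base$parameters,
    system_size = base$system_size)
  rs2 <- reduce_network(net2)
  expect_equal(rs2$net$species$id[rs2$independent][1], "E")
  C2 <- lna(net2)$C
  expect_equal(C2[rownames(C1), colnames(C1)], C1, tolerance = 1e-9)
})

test_that("the reduction report names the conserved sums", {
  rep <- reduction_report(reduce_network(michaelis_menten()))
  expect_match(rep, "\\[SE\\] \\+ \\[E\\]")
  expect_match(rep, "1000")   # beta * omega particles
  expect_equal(reduction_report(reduce_network(birth_death())),
               "no conservation relations")
})
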