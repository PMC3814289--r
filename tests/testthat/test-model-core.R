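# Reaction-network data model: construction, validation, stoichiometry,
# rates and propensities.

test_that("network construction validates the model description", {
  net <- michaelis_menten()
  expect_s3_class(net, "reaction_network")
  expect_equal(nrow(net$species), 4L)       # S, SE, P, E
  expect_equal(length(net$reactions), 5L)
  expect_equal(net$species$id, c("S", "SE", "P", "E"))

  expect_error(reaction_network(data.frame(id = character(),
                                           initial = numeric()),
                                list(reaction("r", c(X = 1), NULL,
                                              rate_expr("1")))),
               "at least one species")
  expect_error(
    reaction_network(data.frame(id = "X", initial = 0),
                     list(reaction("r", c(X = 1), NULL, rate_expr("k * Q"))),
                     parameters = c(k = 1), system_size = 1),
    "Q")
  expect_error(
    reaction_network(data.frame(id = c("X", "X"), initial = c(0, 1)),
                     list(reaction("r", c(X = 1), NULL, rate_expr("X")))),
    "duplicate species")
  expect_error(
    reaction_network(data.frame(id = "X", initial = 0),
                     list(reaction("r", c(X = 1), NULL, rate_expr("X"))),
                     system_size = 0),
    "Omega")
})

test_that("rate laws are restricted to the arithmetic subset", {
  expect_s3_class(rate_expr("V * S / (K + S)"), "rate_law")
  expect_s3_class(rate_expr("k * (A - B)^2"), "rate_law")
  expect_error(rate_expr("exp(x)"), "unsupported operation")
  expect_error(rate_expr("system('ls')"), "unsupported operation")
})

test_that("stoichiometry matrix matches the reaction table", {
  N <- stoichiometry_matrix(michaelis_menten())
  expect_equal(unname(N),
               matrix(c(1, 0, 0, 0,
                        -1, 1, 0, -1,
                        1, -1, 0, 1,
                        0, -1, 1, 1,
                        0, 0, -1, 0), 4, 5),
               ignore_attr = TRUE)
  expect_equal(unname(stoichiometry_matrix(birth_death())),
               matrix(c(1, -1), 1, 2), ignore_attr = TRUE)
  # every reaction changes at least one species
  for (net in list(michaelis_menten(), erk_cascade(), linear_chain())) {
    expect_true(all(colSums(abs(stoichiometry_matrix(net))) >= 1))
  }
})

test_that("macroscopic rates follow the kinetic laws", {
  net <- michaelis_menten(k2 = 2)
  f <- macroscopic_rates(net, c(S = 3, SE = 0.5, P = 0.1, E = 4))
  expect_equal(unname(f[2]), 2 * 3 * 4)     # binding: k2 [S][E]
  f0 <- macroscopic_rates(michaelis_menten(), c(0, 0, 0, 0))
  expect_equal(unname(f0), c(1, 0, 0, 0, 0))  # only the constant influx
  expect_error(macroscopic_rates(net, c(S = NaN, SE = 0, P = 0, E = 0)),
               "non-finite")
  expect_error(macroscopic_rates(net, c(S = -1, SE = 0, P = 0, E = 0)),
               "negative")
  # solver overshoot just below zero is clipped, not an error
  expect_silent(macroscopic_rates(net, c(S = -1e-13, SE = 0, P = 0, E = 0)))
})

test_that("flux balance holds at the analytic steady state", {
  beta <- 10; k <- c(1, 1, 1, 1, 1)
  x2 <- k[1] / k[4]
  xstar <- c(S = (k[1] * k[3] + k[1] * k[4]) / (k[2] * k[4] * (beta - x2)),
             SE = x2, P = k[1] / k[5], E = beta - x2)
  f <- macroscopic_rates(michaelis_menten(), xstar)
  expect_equal(unname(f[2]), unname(f[3] + f[4]), tolerance = 1e-12)
})

test_that("propensities are the density-form master-equation rates", {
  net <- birth_death(k = 5, d = 0.5, omega = 10)
  expect_equal(unname(propensities(net, 20)), c(10 * 5, 20 * 0.5))
  p0 <- propensities(michaelis_menten(), c(0, 0, 0, 0))
  expect_true(p0[1] > 0 && all(p0[-1] == 0))
  expect_error(propensities(net, -1), "non-negative")
  # Omega-scaling identity: T/Omega = f(n/Omega) for mass action
  for (om in c(1, 10, 1000)) {
    neto <- birth_death(k = 5, d = 0.5, omega = om)
    n <- round(om * 7)
    expect_equal(propensities(neto, n) / om,
                 macroscopic_rates(neto, n / om), ignore_attr = TRUE)
  }
})

test_that("matrix drift equals the hand-written rate equations", {
  net <- michaelis_menten()
  set.seed(11)
  for (i in 1:20) {
    x <- stats::runif(4, 0, 5)
    names(x) <- net$species$id
    expect_equal(unname(drift(net, x)), mm_rhs(x), tolerance = 1e-12)
  }
})

test_that("reversible splitting preserves the deterministic dynamics", {
  rev_net <- reaction_network(
    species = data.frame(id = c("A", "B"), initial = c(2, 1)),
    reactions = list(
      reaction("iso", c(A = 1), c(B = 1), rate_expr("kf * A - kr * B"),
               reversible = TRUE),
      reaction("in", NULL, c(A = 1), rate_expr("s")),
      reaction("out", c(B = 1), NULL, rate_expr("d * B"))
    ),
    parameters = c(kf = 2, kr = 0.5, s = 1, d = 1), system_size = 10)

  split <- split_reversible(rev_net)
  expect_true(all(!vapply(split$reactions, `[[`, TRUE, "reversible")))
  expect_equal(length(split$reactions), length(rev_net$reactions) + 1L)
  # the two split columns are exact negations of each other
  N <- stoichiometry_matrix(split)
  expect_equal(N[, "iso_fwd"], -N[, "iso_rev"])
  # forward/backward parts land on the right reactions
  f <- macroscopic_rates(split, c(A = 3, B = 2))
  expect_equal(unname(f[c("iso_fwd", "iso_rev")]), c(2 * 3, 0.5 * 2))
  # deterministic drift unchanged at random states
  set.seed(21)
  for (i in 1:10) {
    x <- stats::runif(2, 0, 4)
    d_orig <- c(1 - (2 * x[1] - 0.5 * x[2]),
                (2 * x[1] - 0.5 * x[2]) - x[2])
    expect_equal(unname(drift(split, x)), d_orig, tolerance = 1e-12)
  }

  # identity on an all-irreversible network
  expect_identical(split_reversible(michaelis_menten()),
                   michaelis_menten())
  # non-separable reversible laws are refused with advice
  bad <- reaction_network(
    species = data.frame(id = c("A", "B"), initial = c(1, 1)),
    reactions = list(reaction("r", c(A = 1), c(B = 1),
                              rate_expr("k * (A / B - 1)"),
                              reversible = TRUE)),
    parameters = c(k = 1), system_size = 1)
  expect_error(split_reversible(bad), "manually")
})

test_that("lna refuses reversible reactions with actionable advice", {
  rev_net <- reaction_network(
    species = data.frame(id = c("A", "B"), initial = c(2, 1)),
    reactions = list(reaction("iso", c(A = 1), c(B = 1),
                              rate_expr("kf * A - kr * B"),
                              reversible = TRUE)),
    parameters = c(kf = 2, kr = 0.5), system_size = 10)
  expect_error(lna(rev_net), "split_reversible")
})
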