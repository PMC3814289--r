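# Independent oracles and small fixtures used across the suite.

# Brute-force Lyapunov solve: vectorise A C + C A^T + omega B = 0 as
# (I (x) A + A (x) I) vec(C) = -omega vec(B). O(K^6) but exact for small K;
# deliberately independent of the package's Schur-based solver.
lyap_kron <- function(A, B, omega = 1) {
  K <- nrow(A)
  matrix(solve(diag(K) %x% A + A %x% diag(K), -omega * as.vector(B)), K, K)
}

# random asymptotically stable matrix (eigenvalues shifted left)
random_stable <- function(K) {
  A <- matrix(stats::rnorm(K * K), K)
  A - diag(K) * (max(Re(eigen(A, only.values = TRUE)$values)) +
                   stats::runif(1, 0.2, 1))
}

# closed mass-action cycle A -> B -> C -> A (one conserved total, no flux
# in or out)
cycle_network <- function(ka = 1, kb = 2, kc = 3, omega = 50) {
  reaction_network(
    species = data.frame(id = c("A", "B", "C"), initial = c(3, 2, 1)),
    reactions = list(
      reaction("ab", c(A = 1), c(B = 1), mass_action("ka")),
      reaction("bc", c(B = 1), c(C = 1), mass_action("kb")),
      reaction("ca", c(C = 1), c(A = 1), mass_action("kc"))
    ),
    parameters = c(ka = ka, kb = kb, kc = kc), system_size = omega)
}

# hand-written macroscopic ODE right-hand side of the Michaelis-Menten
# system, x = (S, SE, P, E), independent transcription of the rate table
mm_rhs <- function(x, k = c(1, 1, 1, 1, 1)) {
  x <- unname(x)
  c(k[1] - k[2] * x[1] * x[4] + k[3] * x[2],
    k[2] * x[1] * x[4] - (k[3] + k[4]) * x[2],
    k[4] * x[2] - k[5] * x[3],
    (k[3] + k[4]) * x[2] - k[2] * x[1] * x[4])
}

# reduced (S, SE, P) right-hand side after eliminating E = beta - SE
mm_rhs_reduced <- function(x, beta, k = c(1, 1, 1, 1, 1)) {
  c(k[1] - k[2] * x[1] * (beta - x[2]) + k[3] * x[2],
    k[2] * x[1] * (beta - x[2]) - (k[3] + k[4]) * x[2],
    k[4] * x[2] - k[5] * x[3])
}

# minimal stand-in lna_result for statistic tests on a prescribed
# covariance matrix and mean vector
fake_lna_result <- function(C, means) {
  dimnames(C) <- list(names(means), names(means))
  structure(list(C = C, means = means), class = "lna_result")
}

# the Michaelis-Menten parameter set used for LNA-vs-SSA validation:
# appreciable correlations between every species pair and steady-state
# means of order 10^2, so ergodic covariance estimates converge in
# reasonable simulated time
mm_validation <- function(omega = 300)
  michaelis_menten(k1 = 1, k2 = 4, k3 = 0.5, k4 = 2.5, k5 = 3.5,
                   beta = 0.75, omega = omega)
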