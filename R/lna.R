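# lna_engine: stationary linear noise approximation about a stable steady
# state. The fluctuation covariance of the reduced system solves the
# Lyapunov equation  A C + C A^T + Omega B = 0, with
#   A_ij = sum_mu nu_imu df_mu/dx_j   (drift Jacobian),
#   B_ij = sum_mu nu_imu nu_jmu f_mu  (diffusion matrix),
# both evaluated at the steady state with dependent species substituted via
# the conservation relations. The full-system covariance is recovered
# through the link matrix, C_full = L C_red L^T, which forces conserved
# totals to have exactly zero variance.

#' Drift matrix A at a steady state
#'
#' @param rs A [reduce_network()] result.
#' @param x_ind Steady-state densities of the independent species.
#' @param params Parameter values; defaults to the network's.
#' @return K x K matrix `A` (analytic differentiation of the rate laws,
#'   chained through the conservation relations).
#' @export
drift_matrix <- function(rs, x_ind, params = rs$net$parameters) {
  A <- drift_jacobian_reduced(rs, x_ind, params)
  dimnames(A) <- list(rs$net$species$id[rs$independent],
                      rs$net$species$id[rs$independent])
  A
}

#' Diffusion matrix B at a steady state
#'
#' @inheritParams drift_matrix
#' @return K x K symmetric positive semidefinite matrix
#'   `B = N_red diag(f) N_red^T`.
#' @export
diffusion_matrix <- function(rs, x_ind, params = rs$net$parameters) {
  f <- macroscopic_rates(rs$net, full_state(rs, x_ind), params)
  B <- rs$N_red %*% (t(rs$N_red) * f)
  dimnames(B) <- list(rs$net$species$id[rs$independent],
                      rs$net$species$id[rs$independent])
  B
}

#' Solve the stationary Lyapunov equation
#'
#' Solves `A C + C A^T + Omega B = 0` by the Bartels-Stewart method: `A` is
#' brought to real Schur form (via [Matrix::Schur()]) and the transformed
#' equation is solved by quasi-triangular back-substitution over the 1x1/2x2
#' Schur blocks. `A` must be asymptotically stable -- otherwise the solution
#' is not unique and the call errors.
#'
#' @param A Stable K x K drift matrix.
#' @param B K x K positive semidefinite diffusion matrix.
#' @param omega System size multiplying `B`.
#' @return Symmetric K x K covariance matrix with attribute `"residual"`,
#'   the max-norm Lyapunov residual relative to `max|Omega B|`.
#' @export
#' @examples
#' solve_lyapunov(matrix(-1), matrix(2), 1)  # 1x1: C = 1
solve_lyapunov <- function(A, B, omega = 1) {
  A <- as.matrix(A); B <- as.matrix(B)
  K <- nrow(A)
  stopifnot(ncol(A) == K, all(dim(B) == K), all(is.finite(A)), all(is.finite(B)))
  st <- assess_stability(A)
  if (st$max_re > -1e-10 * max(1, max(abs(A))))
    stop("drift matrix is not asymptotically stable (max Re eigenvalue = ",
         format(st$max_re, digits = 4),
         "); the Lyapunov solution is not unique")
  Q <- omega * (B + t(B)) / 2
  sch <- Matrix::Schur(A)
  U <- as.matrix(sch$Q); T_ <- as.matrix(sch$T)
  F_ <- crossprod(U, Q %*% U)          # t(U) %*% Q %*% U
  Y <- sylvester_quasitri(T_, -F_)
  C <- U %*% Y %*% t(U)
  C <- (C + t(C)) / 2
  res <- max(abs(A %*% C + C %*% t(A) + Q)) / max(max(abs(Q)), .Machine$double.xmin)
  if (res > 1e-9)
    warning("Lyapunov residual ", format(res, digits = 3),
            " exceeds 1e-9 of max|Omega B|")
  dimnames(C) <- dimnames(A)
  attr(C, "residual") <- res
  C
}

# solve T Y + Y T^T = F for upper quasi-triangular T (real Schur form)
sylvester_quasitri <- function(T_, F_) {
  K <- nrow(T_)
  # block boundaries: a 2x2 block where the subdiagonal is non-negligible
  tolsub <- 1e-12 * max(1, max(abs(T_)))
  starts <- integer(0); k <- 1L
  while (k <= K) {
    starts <- c(starts, k)
    k <- k + if (k < K && abs(T_[k + 1L, k]) > tolsub) 2L else 1L
  }
  ends <- c(starts[-1L] - 1L, K)
  nb <- length(starts)
  Y <- matrix(0, K, K)
  for (jb in nb:1) {
    jj <- starts[jb]:ends[jb]
    for (ib in nb:1) {
      ii <- starts[ib]:ends[ib]
      R <- F_[ii, jj, drop = FALSE]
      if (ends[ib] < K) {
        kk <- (ends[ib] + 1L):K
        R <- R - T_[ii, kk, drop = FALSE] %*% Y[kk, jj, drop = FALSE]
      }
      if (ends[jb] < K) {
        ll <- (ends[jb] + 1L):K
        R <- R - Y[ii, ll, drop = FALSE] %*% t(T_[jj, ll, drop = FALSE])
      }
      ni <- length(ii); nj <- length(jj)
      M <- diag(nj) %x% T_[ii, ii, drop = FALSE] +
        T_[jj, jj, drop = FALSE] %x% diag(ni)
      Y[ii, jj] <- matrix(solve(M, as.vector(R)), ni, nj)
    }
  }
  Y
}

#' Expand a reduced covariance to the full species set
#'
#' @param C_red K x K covariance of the independent species.
#' @param L Khat x K link matrix (rows in the desired species order).
#' @return Khat x Khat covariance `L C_red L^T`.
#' @export
expand_covariance <- function(C_red, L) {
  stopifnot(ncol(L) == nrow(C_red), nrow(C_red) == ncol(C_red))
  C <- L %*% C_red %*% t(L)
  (C + t(C)) / 2
}

#' Linear noise approximation of a reaction network
#'
#' Runs the full pipeline: conserved-moiety reduction, steady-state search,
#' drift and diffusion matrices, Schur-based Lyapunov solve, and covariance
#' recovery for all species. Covariances are reported in particles^2 and
#' means in particles; the density-scale covariance `Xi = C_red / Omega` is
#' attached for concentration-based work.
#'
#' @param net An irreversible [reaction_network()] (reversible reactions
#'   error with an instruction to [split_reversible()] first).
#' @param params Optional named parameter overrides.
#' @param x0 Optional start densities for the steady-state search
#'   (independent species).
#' @param stability_margin Warn when the dominant eigenvalue real part is
#'   within this fraction of the spectral radius of zero (the
#'   approximation loses accuracy close to a bifurcation); default 1e-3.
#' @return An `lna_result` with `A`, `B`, `Xi`, `C_red`, `C` (full
#'   particle-number covariance, species order as declared), `means`
#'   (particle numbers), `steady_state`, and the `reduced_system`.
#' @export
#' @examples
#' res <- lna(michaelis_menten())
#' res$C["E", "E"]      # var(E) in particles^2
lna <- function(net, params = NULL, x0 = NULL, stability_margin = 1e-3) {
  stopifnot(inherits(net, "reaction_network"))
  stop_if_reversible(net)
  if (!is.null(params)) net <- do.call(set_parameters, c(list(net), as.list(params)))
  rs <- reduce_network(net)
  ss <- find_steady_state(rs, x0 = x0)
  if (!ss$stable)
    stop("steady state is not asymptotically stable (max Re eigenvalue = ",
         format(max(Re(ss$eigenvalues)), digits = 4), ")")
  if (max(Re(ss$eigenvalues)) > -stability_margin * max(abs(ss$eigenvalues)))
    warning("steady state is close to instability (max Re eigenvalue = ",
            format(max(Re(ss$eigenvalues)), digits = 4),
            "); the linear noise approximation loses accuracy near a ",
            "bifurcation")
  A <- drift_matrix(rs, ss$x_ind)
  B <- diffusion_matrix(rs, ss$x_ind)
  C_red <- solve_lyapunov(A, B, net$system_size)
  C_full <- expand_covariance(C_red, rs$L)
  dimnames(C_full) <- list(net$species$id, net$species$id)
  structure(list(A = A, B = B, Xi = C_red / net$system_size, C_red = C_red,
                 C = C_full, means = ss$mean_particles, steady_state = ss,
                 reduced_system = rs, net = net,
                 lyapunov_residual = attr(C_red, "residual")),
            class = "lna_result")
}

#' @export
print.lna_result <- function(x, ...) {
  cat("<lna_result> ", x$net$name, ": ", length(x$means),
      " species, Omega = ", format(x$net$system_size), "\n", sep = "")
  cat("steady-state particle numbers:\n")
  print(round(x$means, 3))
  cat("particle-number covariance:\n")
  print(round(x$C, 4))
  invisible(x)
}
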