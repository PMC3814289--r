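# steady_state: locate an asymptotically stable fixed point of the reduced
# deterministic system and classify its stability.
#
# Strategy: damped Newton (analytic Jacobian) from the supplied start; on
# failure, integrate the stiff ODEs for a long horizon with deSolve::lsoda
# and re-run Newton from the endpoint; a remaining failure is reported as a
# distinguishable "no steady state found" condition that the closed loop
# converts into an infeasible evaluation rather than an exception.

#' Find a steady state of the reduced system
#'
#' @param rs A [reduce_network()] result.
#' @param x0 Starting densities for the independent species (defaults to the
#'   network's initial densities).
#' @param tol Relative residual tolerance: convergence requires
#'   `max|dx/dt| < tol * max(characteristic flux, 1)` where the
#'   characteristic flux is the largest reaction rate at the solution.
#' @param max_iter Newton iteration cap.
#' @param integrate_time Horizon for the integration fallback.
#' @param params Parameter values; defaults to the network's.
#' @return A `steady_state` object: `x_ind`, full densities `x`,
#'   `mean_particles` (`Omega * x`), `residual`, `eigenvalues` of the reduced
#'   drift Jacobian, and `stable` (all real parts negative).
#' @export
#' @examples
#' rs <- reduce_network(michaelis_menten())
#' find_steady_state(rs)
find_steady_state <- function(rs, x0 = NULL, tol = 1e-9, max_iter = 200L,
                              integrate_time = 1e6,
                              params = rs$net$parameters) {
  stopifnot(inherits(rs, "reduced_system"))
  if (is.null(x0)) x0 <- rs$net$species$initial[rs$independent]
  x0 <- pmax(as.numeric(x0), 0)
  if (length(x0) != rs$K) stop("x0 must have length K = ", rs$K)

  sol <- newton_steady(rs, x0, tol, max_iter, params)
  # staged fallback: relax the ODEs over increasing horizons, retrying
  # Newton from each endpoint (short horizons usually suffice and are cheap)
  x <- x0
  for (horizon in c(integrate_time / 1000, integrate_time / 100,
                    integrate_time / 10, integrate_time)) {
    if (!is.null(sol)) break
    x <- tryCatch(integrate_to_rest(rs, x, horizon, params),
                  error = function(e) NULL)
    if (is.null(x)) break
    sol <- newton_steady(rs, x, tol, max_iter, params)
  }
  if (is.null(sol))
    stop("no steady state found (Newton and integration fallback both failed)")

  A <- drift_jacobian_reduced(rs, sol$x, params)
  ev <- eigen(A, only.values = TRUE)$values
  x_full <- full_state(rs, sol$x)
  x_ind <- stats::setNames(sol$x, rs$net$species$id[rs$independent])
  structure(list(x_ind = x_ind, x = x_full,
                 mean_particles = rs$net$system_size * x_full,
                 residual = sol$residual,
                 eigenvalues = ev, stable = max(Re(ev)) < 0),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> residual ", format(x$residual, digits = 3),
      if (x$stable) ", stable" else ", UNSTABLE", "\n", sep = "")
  print(round(rbind(density = x$x, particles = x$mean_particles), 6))
  cat("eigenvalues: ", paste(format(x$eigenvalues, digits = 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

newton_steady <- function(rs, x, tol, max_iter, params) {
  env <- rate_env(rs, params)
  fx <- function(x) {
    f <- tryCatch(rates_fast(rs, full_state(rs, x), env),
                  error = function(e) NULL)
    if (is.null(f) || any(!is.finite(f))) return(NULL)
    list(f = f, d = as.numeric(rs$N_red %*% f))
  }
  ev <- fx(x)
  for (it in seq_len(max_iter)) {
    if (is.null(ev)) return(NULL)
    if (max(abs(ev$d)) < tol * max(max(abs(ev$f)), 1)) {
      if (any(full_state(rs, x) < -1e-12)) return(NULL)
      return(list(x = pmax(x, 0), residual = max(abs(ev$d))))
    }
    Df <- tryCatch(rate_jacobian_fast(rs, full_state(rs, x), env),
                   error = function(e) NULL)
    if (is.null(Df) || any(!is.finite(Df))) return(NULL)
    J <- rs$N_red %*% Df %*% rs$L
    step <- tryCatch(solve(J, -ev$d), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # damp: halve the step until all densities (incl. dependents) stay >= 0
    # and the residual does not blow up
    lam <- 1
    repeat {
      xn <- x + lam * step
      en <- if (all(full_state(rs, xn) >= -1e-12)) fx(xn) else NULL
      ok <- !is.null(en) && max(abs(en$d)) < 2 * max(abs(ev$d)) + tol
      if (ok || lam < 1e-8) break
      lam <- lam / 2
    }
    if (lam < 1e-8) return(NULL)
    x <- pmax(xn, 0)
    ev <- en
  }
  NULL
}

integrate_to_rest <- function(rs, x0, t_end, params) {
  env <- rate_env(rs, params)
  rhs <- function(t, y, p)
    list(as.numeric(rs$N_red %*% rates_fast(rs, full_state(rs, pmax(y, 0)),
                                            env)))
  out <- deSolve::ode(y = x0, times = c(0, t_end), func = rhs,
                      parms = NULL, method = "lsoda", rtol = 1e-7, atol = 1e-9,
                      maxsteps = 50000)
  pmax(as.numeric(out[nrow(out), -1]), 0)
}

#' Assess the linear stability of a drift matrix
#'
#' @param A Square numeric matrix (the drift/Jacobian matrix at a fixed
#'   point).
#' @return List with complex `eigenvalues`, `max_re`, and `stable`
#'   (`TRUE` iff every eigenvalue has a strictly negative real part).
#' @export
assess_stability <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), all(is.finite(A)))
  ev <- eigen(A, only.values = TRUE)$values
  list(eigenvalues = ev, max_re = max(Re(ev)), stable = max(Re(ev)) < 0)
}

#' Locate a stability boundary along one parameter
#'
#' Bisects the sign change of the dominant eigenvalue real part of the
#' reduced drift Jacobian (evaluated at the steady state) as one parameter
#' varies; at a Hopf bifurcation the crossing eigenvalues form a complex
#' conjugate pair, which is detected and reported.
#'
#' @param net An irreversible [reaction_network()].
#' @param param Parameter name.
#' @param interval Numeric length-2 search interval; `max Re(lambda)` must
#'   change sign across it.
#' @param tol Bisection tolerance on the parameter (default 1e-4).
#' @return List with `critical` (the crossing value), `max_re` at both ends,
#'   and `crossing` (`"hopf"` if the dominant eigenvalue at the critical
#'   point is complex, else `"real"`).
#' @export
find_instability_point <- function(net, param, interval, tol = 1e-4) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  maxre <- function(p) {
    n2 <- set_parameters(net, stats::setNames(p, param))
    rs <- reduce_network(n2)
    ss <- find_steady_state(rs)
    list(re = max(Re(ss$eigenvalues)), ev = ss$eigenvalues)
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- maxre(lo); fhi <- maxre(hi)
  if (sign(flo$re) == sign(fhi$re))
    stop("max Re(eigenvalue) does not change sign over the interval [",
         lo, ", ", hi, "]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    fm <- maxre(mid)
    if (sign(fm$re) == sign(flo$re)) { lo <- mid; flo <- fm }
    else { hi <- mid; fhi <- fm }
  }
  crit <- (lo + hi) / 2
  fc <- maxre(crit)
  dom <- fc$ev[which.max(Re(fc$ev))]
  list(critical = crit, max_re_lower = flo$re, max_re_upper = fhi$re,
       crossing = if (abs(Im(dom)) > 1e-8) "hopf" else "real")
}
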