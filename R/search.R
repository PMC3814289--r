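# search: parameter scanning and stochastic global optimisation (particle
# swarm, evolutionary programming) of noise statistics in a closed loop with
# the steady-state + LNA computation.

#' Declare a parameter range
#'
#' @param param Parameter name.
#' @param lower,upper Finite bounds.
#' @param reference Current/reference value (defaults to the midpoint);
#'   must lie within the bounds.
#' @return A `param_range` object.
#' @export
param_range <- function(param, lower, upper, reference = (lower + upper) / 2) {
  stopifnot(is.character(param), length(param) == 1L,
            is.finite(lower), is.finite(upper), lower < upper,
            lower <= reference, reference <= upper)
  structure(list(param = param, lower = lower, upper = upper,
                 reference = reference), class = "param_range")
}

as_ranges <- function(ranges) {
  if (inherits(ranges, "param_range")) ranges <- list(ranges)
  stopifnot(is.list(ranges), length(ranges) >= 1L,
            all(vapply(ranges, inherits, TRUE, "param_range")))
  ranges
}

#' Scan a noise statistic over a parameter grid
#'
#' Evaluates the closed loop (steady state + LNA + statistic) at every point
#' of a regular grid over 1..n parameter ranges. Points where the
#' evaluation fails (no steady state, unstable, constraint violation) are
#' flagged infeasible, not dropped. Grid order is row-major with the first
#' declared parameter varying slowest.
#'
#' @param net An irreversible [reaction_network()].
#' @param statistic Statistic expression (see [noise_statistic()]) or an
#'   [objective_spec()] (its constraints are then enforced).
#' @param ranges A [param_range()] or list of them.
#' @param points Grid points per dimension (scalar or one per range).
#' @return A tibble with one column per scanned parameter plus `value`,
#'   `feasible` and `reason`; class `lna_scan`.
#' @export
#' @examples
#' sc <- scan_statistic(birth_death(), "var(X)",
#'                      param_range("d", 0.25, 1), points = 5)
#' sc
scan_statistic <- function(net, statistic, ranges, points = 26L) {
  ranges <- as_ranges(ranges)
  points <- rep_len(as.integer(points), length(ranges))
  stopifnot(all(points >= 2L))
  objective <- if (inherits(statistic, "objective_spec")) statistic
               else objective_spec(statistic, "maximise")
  grids <- lapply(seq_along(ranges), function(i)
    seq(ranges[[i]]$lower, ranges[[i]]$upper, length.out = points[i]))
  names(grids) <- vapply(ranges, `[[`, "", "param")
  # first parameter slowest: build the grid with the last parameter cycling fastest
  grid <- rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE))
  ref_means <- reference_means_for(net, objective)
  out <- lapply(seq_len(nrow(grid)), function(r) {
    ev <- evaluate_objective(net, unlist(grid[r, , drop = FALSE]), objective,
                             reference_means = ref_means)
    tibble::tibble(value = if (ev$feasible) ev$value else NA_real_,
                   feasible = ev$feasible, reason = ev$reason)
  })
  res <- dplyr::bind_cols(tibble::as_tibble(grid), dplyr::bind_rows(out))
  attr(res, "statistic") <- objective$statistic
  class(res) <- c("lna_scan", class(res))
  res
}

reference_means_for <- function(net, objective) {
  if (!length(objective$constraints) ||
      !any(vapply(objective$constraints, `[[`, TRUE, "relative"))) return(NULL)
  lna(net)$means
}

#' Plot a 1D or 2D scan
#'
#' @param object An [scan_statistic()] result.
#' @param ... Unused.
#' @return A ggplot: value vs parameter (1D) or a filled tile map (2D).
#' @export
autoplot.lna_scan <- function(object, ...) {
  pars <- setdiff(names(object), c("value", "feasible", "reason"))
  stat <- attr(object, "statistic") %||% "value"
  if (length(pars) == 1L) {
    ggplot2::ggplot(object, ggplot2::aes(.data[[pars[1]]], .data$value)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(y = stat)
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data[[pars[1]]], .data[[pars[2]]],
                                         fill = .data$value)) +
      ggplot2::geom_tile() + ggplot2::scale_fill_viridis_c(name = stat)
  }
}

# ---- optimisers -----------------------------------------------------------
# Both optimisers MINIMISE fn over a box; infeasible evaluations must be
# encoded as +Inf by the caller. Determinism contract: a fixed seed yields a
# bitwise-identical trace (single RNG stream, generation-synchronous).

new_opt_result <- function(best_par, best_value, trace, evals, seed, reason,
                           feasible, method) {
  structure(list(best_parameters = best_par, best_value = best_value,
                 trace = trace, evaluation_count = evals, seed = seed,
                 termination = reason, feasible = feasible, method = method),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat("<opt_result> ", x$method, ": best value ", format(x$best_value),
      if (!x$feasible) " (NO feasible point found)", "\n", sep = "")
  cat("at: ", paste(names(x$best_parameters), "=",
                    signif(x$best_parameters, 6), collapse = ", "), "\n")
  cat(x$evaluation_count, " evaluations, terminated: ", x$termination, "\n",
      sep = "")
  invisible(x)
}

#' Particle swarm optimisation over a box
#'
#' Global-best PSO with the standard constriction coefficients (inertia
#' 0.729, cognitive/social weights 1.49445), velocities clamped to half the
#' box width and positions clipped to the bounds.
#'
#' @param fn Function of a parameter vector returning a scalar to minimise;
#'   return `Inf` for infeasible points.
#' @param lower,upper Numeric bounds (equal length, finite).
#' @param swarm_size Number of particles (>= 2; default 50).
#' @param max_iter Iteration cap.
#' @param seed RNG seed recorded in the result.
#' @param stall_iter,stall_tol Terminate early when the best value has not
#'   improved by a relative `stall_tol` over `stall_iter` iterations.
#' @return An `opt_result`: `best_parameters`, `best_value`, a best-so-far
#'   `trace` tibble, `evaluation_count`, `seed`, `termination`.
#' @export
particle_swarm <- function(fn, lower, upper, swarm_size = 50L, max_iter = 100L,
                           seed = 1L, stall_iter = 25L, stall_tol = 1e-6) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower < upper), swarm_size >= 2L)
  d <- length(lower)
  set.seed(seed)
  w <- 0.729; c1 <- 1.49445; c2 <- 1.49445
  span <- upper - lower
  vmax <- span / 2
  X <- matrix(stats::runif(swarm_size * d, lower, upper), swarm_size, d,
              byrow = TRUE)
  V <- matrix(stats::runif(swarm_size * d, -vmax, vmax), swarm_size, d,
              byrow = TRUE)
  pbest <- X
  pval <- apply(X, 1L, fn)
  evals <- swarm_size
  gb <- which.min(pval)
  gbest <- X[gb, ]; gval <- pval[gb]
  trace <- numeric(max_iter)
  reason <- "max_iter"
  last_improve <- 0L
  for (it in seq_len(max_iter)) {
    r1 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    r2 <- matrix(stats::runif(swarm_size * d), swarm_size, d)
    V <- w * V + c1 * r1 * (pbest - X) +
      c2 * r2 * (matrix(gbest, swarm_size, d, byrow = TRUE) - X)
    V <- pmin(pmax(V, matrix(-vmax, swarm_size, d, byrow = TRUE)),
              matrix(vmax, swarm_size, d, byrow = TRUE))
    X <- X + V
    X <- pmin(pmax(X, matrix(lower, swarm_size, d, byrow = TRUE)),
              matrix(upper, swarm_size, d, byrow = TRUE))
    val <- apply(X, 1L, fn)
    evals <- evals + swarm_size
    imp <- val < pval
    pbest[imp, ] <- X[imp, , drop = FALSE]
    pval[imp] <- val[imp]
    gb <- which.min(pval)
    if (pval[gb] < gval - abs(gval) * stall_tol) last_improve <- it
    if (pval[gb] < gval) { gval <- pval[gb]; gbest <- pbest[gb, ] }
    trace[it] <- gval
    if (it - last_improve >= stall_iter) { reason <- "stall"; trace <- trace[1:it]; break }
  }
  new_opt_result(stats::setNames(gbest, names(lower)), gval,
                 tibble::tibble(iteration = seq_along(trace), best = trace),
                 evals, seed, reason, is.finite(gval), "particle_swarm")
}

#' Evolutionary programming over a box
#'
#' Classical self-adaptive (meta-EP) Gaussian mutation: each individual
#' carries per-parameter step sizes that are mutated log-normally; survivors
#' are picked by stochastic round-robin tournament (q = 10% of the combined
#' population) over parents plus offspring.
#'
#' @inheritParams particle_swarm
#' @param pop_size Population size (>= 2).
#' @param generations Generation cap.
#' @return An `opt_result` (see [particle_swarm()]).
#' @export
evolutionary_programming <- function(fn, lower, upper, pop_size = 20L,
                                     generations = 200L, seed = 1L,
                                     stall_iter = 50L, stall_tol = 1e-6) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(lower < upper), pop_size >= 2L)
  d <- length(lower)
  set.seed(seed)
  span <- upper - lower
  tau <- 1 / sqrt(2 * sqrt(d)); tau2 <- 1 / sqrt(2 * d)
  X <- matrix(stats::runif(pop_size * d, lower, upper), pop_size, d, byrow = TRUE)
  S <- matrix(span / 10, pop_size, d, byrow = TRUE)
  val <- apply(X, 1L, fn)
  evals <- pop_size
  gbest <- X[which.min(val), ]; gval <- min(val)
  trace <- numeric(generations)
  reason <- "max_generations"
  last_improve <- 0L
  q <- max(2L, round(0.1 * 2 * pop_size))
  for (g in seq_len(generations)) {
    g0 <- stats::rnorm(pop_size)
    Xo <- X + S * matrix(stats::rnorm(pop_size * d), pop_size, d)
    Xo <- pmin(pmax(Xo, matrix(lower, pop_size, d, byrow = TRUE)),
               matrix(upper, pop_size, d, byrow = TRUE))
    So <- S * exp(tau2 * g0 + tau * matrix(stats::rnorm(pop_size * d),
                                           pop_size, d))
    So <- pmin(pmax(So, matrix(span * 1e-8, pop_size, d, byrow = TRUE)),
               matrix(span, pop_size, d, byrow = TRUE))
    valo <- apply(Xo, 1L, fn)
    evals <- evals + pop_size
    allX <- rbind(X, Xo); allS <- rbind(S, So); allv <- c(val, valo)
    # round-robin tournament: wins against q random opponents
    wins <- vapply(seq_len(2 * pop_size), function(i) {
      opp <- sample.int(2 * pop_size, q)
      sum(allv[i] <= allv[opp])
    }, integer(1))
    keep <- order(-wins, allv)[seq_len(pop_size)]
    X <- allX[keep, , drop = FALSE]; S <- allS[keep, , drop = FALSE]
    val <- allv[keep]
    if (min(val) < gval - abs(gval) * stall_tol) last_improve <- g
    if (min(val) < gval) { gval <- min(val); gbest <- X[which.min(val), ] }
    trace[g] <- gval
    if (g - last_improve >= stall_iter) { reason <- "stall"; trace <- trace[1:g]; break }
  }
  new_opt_result(stats::setNames(gbest, names(lower)), gval,
                 tibble::tibble(iteration = seq_along(trace), best = trace),
                 evals, seed, reason, is.finite(gval), "evolutionary_programming")
}

#' Optimise a noise objective over parameter ranges
#'
#' Runs the closed loop {set parameters -> steady state -> LNA -> statistic,
#' constraints} under a global optimiser. Infeasible evaluations (unstable or
#' absent steady states, violated constraints) are treated as always-worse
#' sentinels and recorded, never raised.
#'
#' @param net An irreversible [reaction_network()].
#' @param objective An [objective_spec()] (or a statistic string, maximised).
#' @param ranges A [param_range()] or list of them.
#' @param method `"particle_swarm"` or `"evolutionary_programming"`.
#' @param seed RNG seed.
#' @param ... Passed to the optimiser (swarm_size, max_iter, pop_size, ...).
#' @return An `opt_result`; `best_value` is on the objective's own scale
#'   (sign corrected for maximisation) and `n_infeasible` counts rejected
#'   evaluations.
#' @export
#' @examples
#' \donttest{
#' opt <- optimise_noise(birth_death(), objective_spec("var(X)", "minimise"),
#'                       param_range("d", 0.25, 1), seed = 1,
#'                       swarm_size = 10, max_iter = 20)
#' }
optimise_noise <- function(net, objective, ranges,
                           method = c("particle_swarm",
                                      "evolutionary_programming"),
                           seed = 1L, ...) {
  method <- match.arg(method)
  if (is.character(objective)) objective <- objective_spec(objective, "maximise")
  ranges <- as_ranges(ranges)
  lower <- stats::setNames(vapply(ranges, `[[`, 0, "lower"),
                           vapply(ranges, `[[`, "", "param"))
  upper <- vapply(ranges, `[[`, 0, "upper")
  sign <- if (objective$direction == "maximise") -1 else 1
  ref_means <- reference_means_for(net, objective)
  n_infeasible <- 0L
  fn <- function(p) {
    ev <- evaluate_objective(net, stats::setNames(p, names(lower)), objective,
                             reference_means = ref_means)
    if (!ev$feasible) {
      n_infeasible <<- n_infeasible + 1L
      return(Inf)
    }
    sign * ev$value
  }
  res <- switch(method,
    particle_swarm = particle_swarm(fn, lower, upper, seed = seed, ...),
    evolutionary_programming = evolutionary_programming(fn, lower, upper,
                                                        seed = seed, ...))
  res$best_value <- sign * res$best_value
  res$trace$best <- sign * res$trace$best
  res$direction <- objective$direction
  res$n_infeasible <- n_infeasible
  res
}
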