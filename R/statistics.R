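# noise_statistics: covariance-based statistics over an lna_result and
# constrained objective evaluation for the closed loop.

#' Evaluate a noise statistic on an LNA result
#'
#' The statistic is an arithmetic expression over the accessor functions
#' `var(X)`, `cov(X, Y)`, `corr(X, Y)`, `cv(X)`, `fano(X)` and `mean(X)`,
#' where `X`/`Y` are species ids (bare or quoted). Everything is on the
#' particle-number scale: `corr = cov / sqrt(var_i var_j)`,
#' `cv = sqrt(var) / mean`, `fano = var / mean`.
#'
#' @param result An [lna()] result.
#' @param statistic Character expression, e.g. `"var(MKKK)"` or
#'   `"cov(A, B) / mean(A)"`.
#' @return Numeric scalar.
#' @export
#' @examples
#' res <- lna(birth_death())
#' noise_statistic(res, "fano(X)")   # 1: Poisson
noise_statistic <- function(result, statistic) {
  stopifnot(inherits(result, "lna_result"), is.character(statistic),
            length(statistic) == 1L)
  C <- result$C
  mu <- result$means
  idx <- function(s) {
    s <- as.character(s)
    if (!s %in% rownames(C)) stop("unknown species `", s, "` in statistic")
    s
  }
  # a steady-state mean below ~1e-8 particles is physically zero; relative
  # statistics are undefined there (and the Gaussian approximation has long
  # since broken down at such boundaries)
  need_pos_mean <- function(i, what) {
    if (mu[i] <= 1e-8)
      stop(what, "(", i, ") undefined: steady-state mean is ",
           format(mu[i]), " particles (effectively zero)")
  }
  env <- new.env(parent = baseenv())
  assign("var", function(x) C[idx(substitute(x)), idx(substitute(x))], envir = env)
  assign("cov", function(x, y) C[idx(substitute(x)), idx(substitute(y))], envir = env)
  assign("corr", function(x, y) {
    i <- idx(substitute(x)); j <- idx(substitute(y))
    if (C[i, i] <= 0 || C[j, j] <= 0)
      stop("corr(", i, ", ", j, ") undefined: a variance is zero")
    C[i, j] / sqrt(C[i, i] * C[j, j])
  }, envir = env)
  assign("cv", function(x) {
    i <- idx(substitute(x)); need_pos_mean(i, "cv")
    sqrt(C[i, i]) / mu[i]
  }, envir = env)
  assign("fano", function(x) {
    i <- idx(substitute(x)); need_pos_mean(i, "fano")
    C[i, i] / mu[i]
  }, envir = env)
  assign("mean", function(x) mu[idx(substitute(x))], envir = env)
  v <- eval(str2lang(statistic), envir = env)
  if (!is.numeric(v) || length(v) != 1L)
    stop("statistic did not evaluate to a scalar")
  as.numeric(v)
}

#' Steady-state particle-number constraint
#'
#' @param species Species id.
#' @param min,max Bounds on the steady-state particle number. With
#'   `relative = TRUE` they are fractions of the species' reference mean
#'   (e.g. `min = 0.5, max = 2` keeps the mean within 50%-200% of its
#'   original value); otherwise absolute particle numbers.
#' @param relative Interpret the bounds as fractions of a reference value.
#' @return A `noise_constraint` object.
#' @export
constraint <- function(species, min = 0, max = Inf, relative = FALSE) {
  stopifnot(is.character(species), length(species) == 1L, min <= max)
  structure(list(species = species, min = min, max = max,
                 relative = isTRUE(relative)), class = "noise_constraint")
}

#' Objective specification for the closed loop
#'
#' @param statistic A statistic expression (see [noise_statistic()]).
#' @param direction `"maximise"` or `"minimise"`.
#' @param constraints List of [constraint()]s on steady-state particle
#'   numbers. Relative constraints are resolved against reference means
#'   captured once from the unmodified model at evaluation setup.
#' @return An `objective_spec` object.
#' @export
objective_spec <- function(statistic, direction = c("maximise", "minimise"),
                           constraints = list()) {
  direction <- match.arg(direction)
  stopifnot(is.list(constraints),
            all(vapply(constraints, inherits, TRUE, "noise_constraint")))
  structure(list(statistic = statistic, direction = direction,
                 constraints = constraints), class = "objective_spec")
}

#' Evaluate a constrained objective at a parameter assignment
#'
#' The closed-loop evaluation: set parameters, run the LNA, evaluate the
#' statistic, and check the steady-state constraints. Failures (no steady
#' state, instability, rate-law singularities, violated constraints) never
#' raise; they return a sentinel worst value (`-Inf` when maximising,
#' `+Inf` when minimising) together with the reason.
#'
#' @param net An irreversible [reaction_network()].
#' @param assignment Named numeric vector of parameter values.
#' @param objective An [objective_spec()].
#' @param reference_means Named particle-number means used to resolve
#'   relative constraints; computed from `net` at its current parameters if
#'   omitted.
#' @return List with `value`, `feasible`, `reason` (`NA` when feasible) and
#'   `result` (the `lna_result`, or `NULL` on failure).
#' @export
evaluate_objective <- function(net, assignment, objective,
                               reference_means = NULL) {
  stopifnot(inherits(objective, "objective_spec"))
  sentinel <- if (objective$direction == "maximise") -Inf else Inf
  fail <- function(reason)
    list(value = sentinel, feasible = FALSE, reason = reason, result = NULL)

  if (is.null(reference_means) && length(objective$constraints) &&
      any(vapply(objective$constraints, `[[`, TRUE, "relative"))) {
    ref <- tryCatch(lna(net), error = function(e) NULL)
    if (is.null(ref)) return(fail("reference model has no stable steady state"))
    reference_means <- ref$means
  }

  res <- tryCatch(lna(net, params = assignment), error = function(e) e)
  if (inherits(res, "error")) return(fail(conditionMessage(res)))

  for (cs in objective$constraints) {
    m <- res$means[cs$species]
    if (is.na(m)) return(fail(paste0("unknown species in constraint: ", cs$species)))
    lo <- cs$min; hi <- cs$max
    if (cs$relative) {
      r <- reference_means[cs$species]
      lo <- lo * r; hi <- hi * r
    }
    if (m < lo || m > hi)
      return(fail(sprintf("constraint violated: mean(%s) = %.4g outside [%.4g, %.4g]",
                          cs$species, m, lo, hi)))
  }

  v <- tryCatch(noise_statistic(res, objective$statistic), error = function(e) e)
  if (inherits(v, "error")) return(fail(conditionMessage(v)))
  list(value = v, feasible = TRUE, reason = NA_character_, result = res)
}
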