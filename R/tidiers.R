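# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy an LNA result into a pairwise covariance table
#'
#' @param x An [lna()] result.
#' @param ... Unused.
#' @return A tibble with one row per unordered species pair: `species_i`,
#'   `species_j`, `covariance` (particles^2) and, on the diagonal,
#'   `cv` and `fano` (NA where the mean is zero).
#' @export
tidy.lna_result <- function(x, ...) {
  ids <- rownames(x$C)
  pr <- which(upper.tri(x$C, diag = TRUE), arr.ind = TRUE)
  out <- tibble::tibble(
    species_i = ids[pr[, 1]], species_j = ids[pr[, 2]],
    covariance = x$C[pr])
  diagv <- out$species_i == out$species_j
  m <- x$means[out$species_i]
  out$cv <- ifelse(diagv & m > 0, sqrt(pmax(out$covariance, 0)) / m, NA_real_)
  out$fano <- ifelse(diagv & m > 0, out$covariance / m, NA_real_)
  out
}

#' One-row summary of an LNA result
#'
#' @param x An [lna()] result.
#' @param ... Unused.
#' @return A tibble with the problem dimensions, system size, steady-state
#'   residual, stability margin and Lyapunov residual.
#' @export
glance.lna_result <- function(x, ...) {
  tibble::tibble(
    n_species = length(x$means),
    n_independent = x$reduced_system$K,
    n_conserved = x$reduced_system$Lambda,
    omega = x$net$system_size,
    residual = x$steady_state$residual,
    max_re_eigenvalue = max(Re(x$steady_state$eigenvalues)),
    lyapunov_residual = x$lyapunov_residual,
    total_variance = sum(diag(x$C)))
}

#' Tidy an optimisation result (best-so-far trace)
#'
#' @param x An `opt_result` from [particle_swarm()],
#'   [evolutionary_programming()] or [optimise_noise()].
#' @param ... Unused.
#' @return The per-iteration best-so-far tibble.
#' @export
tidy.opt_result <- function(x, ...) x$trace

#' One-row summary of an optimisation result
#'
#' @param x An `opt_result`.
#' @param ... Unused.
#' @return A tibble: best value, evaluation count, seed, termination reason.
#' @export
glance.opt_result <- function(x, ...) {
  tibble::tibble(method = x$method, best_value = x$best_value,
                 evaluation_count = x$evaluation_count,
                 iterations = nrow(x$trace), seed = x$seed,
                 termination = x$termination, feasible = x$feasible)
}

#' Plot the best-so-far trace of an optimisation
#'
#' @param object An `opt_result`.
#' @param ... Unused.
#' @return A ggplot of best objective value per iteration.
#' @export
autoplot.opt_result <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(.data$iteration, .data$best)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best objective value",
                  title = object$method)
}

#' Plot an SSA trajectory
#'
#' @param object An [gillespie_direct()] trajectory.
#' @param species Species ids to show (default: all).
#' @param ... Unused.
#' @return A step-plot ggplot of particle numbers vs time.
#' @export
autoplot.ssa_trajectory <- function(object, species = NULL, ...) {
  df <- tibble::as_tibble(as.data.frame(object$states))
  df$time <- object$times
  long <- tidyr_pivot(df, setdiff(names(df), "time"))
  if (!is.null(species)) long <- long[long$species %in% species, ]
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$particles,
                                     colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "particle number")
}

# local long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot <- function(df, cols) {
  do.call(rbind, lapply(cols, function(cn)
    data.frame(time = df$time, species = cn, particles = df[[cn]])))
}
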