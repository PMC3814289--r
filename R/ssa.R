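# ssa_oracle: exact stochastic simulation (Gillespie Direct Method) and
# stationary moment estimation, the independent check on the LNA
# covariances. Networks whose rate laws are all mass action run in a
# compiled kernel; general kinetics fall back to an R event loop.

all_mass_action <- function(net)
  all(vapply(net$reactions, function(r) r$rate$kind == "mass_action", TRUE))

reactant_matrix <- function(net) {
  R <- matrix(0L, nrow(net$species), length(net$reactions),
              dimnames = list(net$species$id,
                              vapply(net$reactions, `[[`, "", "id")))
  for (m in seq_along(net$reactions)) {
    r <- net$reactions[[m]]
    R[names(r$reactants), m] <- as.integer(r$reactants)
  }
  R
}

#' Simulate one exact SSA trajectory
#'
#' Gillespie's Direct Method: exponential waiting times with rate equal to
#' the total propensity and reaction selection proportional to individual
#' propensities, with the density-form propensities of [propensities()].
#'
#' @param net An irreversible [reaction_network()].
#' @param n0 Initial integer particle numbers (defaults to the rounded
#'   initial densities times Omega).
#' @param t_end Simulated time horizon.
#' @param seed RNG seed (recorded in the trajectory).
#' @param max_record Cap on recorded events (the simulation itself is not
#'   truncated by this; later events simply go unrecorded).
#' @param max_events Hard cap on simulated events.
#' @return An `ssa_trajectory`: `times` (event times, starting at 0),
#'   `states` (one row per recorded event), `final_state`, `t_end`,
#'   `absorbed` (all propensities hit zero), `seed`.
#' @export
#' @examples
#' tr <- gillespie_direct(birth_death(), t_end = 5, seed = 42)
#' head(tr$states)
gillespie_direct <- function(net, n0 = NULL, t_end, seed = 1L,
                             max_record = 1e6, max_events = 5e8) {
  stop_if_reversible(net)
  if (is.null(n0)) n0 <- round(net$system_size * net$species$initial)
  n0 <- order_by_species(net, n0)
  if (any(n0 < 0) || any(n0 != round(n0)))
    stop("n0 must be non-negative integers")
  set.seed(seed)
  raw <- if (all_mass_action(net)) {
    ssa_mass_action_cpp(stoichiometry_matrix(net), reactant_matrix(net),
                        vapply(net$reactions,
                               function(r) net$parameters[[r$rate$constant]],
                               0),
                        net$system_size, n0, t_end, burn_in = 0,
                        n_blocks = 1L, record = TRUE,
                        max_record = as.integer(max_record), max_events)
  } else {
    ssa_r_loop(net, n0, t_end, max_record, max_events)
  }
  states <- raw$states
  colnames(states) <- net$species$id
  structure(list(times = raw$times, states = states,
                 final_state = stats::setNames(raw$final_state,
                                               net$species$id),
                 t_end = t_end, t_final = raw$t_final,
                 n_events = raw$n_events, absorbed = raw$absorbed,
                 truncated = isTRUE(raw$truncated), seed = seed, net = net),
            class = "ssa_trajectory")
}

#' @export
print.ssa_trajectory <- function(x, ...) {
  cat("<ssa_trajectory> ", format(x$n_events, big.mark = ","),
      " events over t = [0, ", format(x$t_final), "]",
      if (x$absorbed) ", ABSORBED", ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# pure-R Direct Method for general kinetics
ssa_r_loop <- function(net, n0, t_end, max_record, max_events) {
  omega <- net$system_size
  exprs <- lapply(net$reactions,
                  function(r) rate_law_expr(r$rate, r$reactants))
  pars <- as.list(net$parameters)
  N <- stoichiometry_matrix(net)
  n <- n0
  t <- 0
  times <- numeric(1); states <- matrix(n, 1, length(n))
  events <- 0; absorbed <- FALSE; truncated <- FALSE
  env <- list2env(pars, parent = baseenv())
  while (t < t_end) {
    x <- n / omega
    for (i in seq_along(x)) assign(names(n)[i], x[i], envir = env)
    props <- omega * vapply(exprs, function(e) eval(e, env), 0)
    a0 <- sum(props)
    if (a0 <= 0) { absorbed <- TRUE; break }
    t2 <- t + stats::rexp(1, a0)
    if (t2 >= t_end) { t <- t_end; break }
    mu <- sample.int(length(props), 1L, prob = props)
    n <- n + N[, mu]
    t <- t2
    events <- events + 1
    if (nrow(states) < max_record) {
      times <- c(times, t); states <- rbind(states, n)
    }
    if (events >= max_events) { truncated <- TRUE; break }
  }
  list(times = times, states = states, final_state = n, n_events = events,
       absorbed = absorbed, truncated = truncated, t_final = min(t, t_end))
}

#' Time-weighted stationary moments of a trajectory
#'
#' The state is piecewise constant between events; moments are the
#' time-weighted (ergodic) averages over `(burn_in, t_end]`.
#'
#' @param traj An [gillespie_direct()] trajectory.
#' @param burn_in Initial time span to discard (must be < `t_end`).
#' @return A `moment_estimate`: `mean`, `cov` (time-weighted), `window`
#'   (effective averaged time), `burn_in`.
#' @export
stationary_moments <- function(traj, burn_in = 0.1 * traj$t_end) {
  stopifnot(inherits(traj, "ssa_trajectory"))
  if (length(traj$times) < traj$n_events + 1)
    warning("trajectory recording was capped; moments cover the recorded ",
            "events only")
  t_end <- traj$t_final
  if (burn_in >= t_end)
    stop("burn_in (", burn_in, ") must be smaller than the trajectory end (",
         t_end, ")")
  tt <- traj$times
  S <- traj$states
  # interval of state i: [tt[i], tt[i+1]), last state holds to t_end
  lo <- pmax(tt, burn_in)
  hi <- pmin(c(tt[-1], t_end), t_end)
  w <- pmax(hi - lo, 0)
  keep <- w > 0
  w <- w[keep]; S <- S[keep, , drop = FALSE]
  W <- sum(w)
  mu <- colSums(S * w) / W
  D <- sweep(S, 2, mu)
  covm <- crossprod(D, D * w) / W
  covm <- (covm + t(covm)) / 2
  structure(list(mean = mu, cov = covm, window = W, burn_in = burn_in),
            class = "moment_estimate")
}

#' Long-run stationary moments with batch-means errors
#'
#' Runs the SSA without trajectory recording and accumulates time-weighted
#' first and second moments in `n_blocks` equal-width batches over
#' `(burn_in, t_end]`; batch scatter yields standard errors for every
#' covariance entry. The initial state defaults to the rounded LNA
#' steady-state particle numbers to shorten the transient.
#'
#' @inheritParams gillespie_direct
#' @param burn_in Time discarded before averaging (default 10% of `t_end`).
#' @param n_blocks Number of batches (default 20).
#' @return A `moment_estimate` with `mean`, `cov`, `se_cov` (batch-means
#'   standard error per covariance entry), `se_mean`, `window`, `n_events`.
#' @export
ssa_moments <- function(net, t_end, burn_in = 0.1 * t_end, n0 = NULL,
                        seed = 1L, n_blocks = 20L, max_events = 5e8) {
  stop_if_reversible(net)
  stopifnot(burn_in < t_end, n_blocks >= 2L)
  if (is.null(n0)) {
    n0 <- tryCatch(round(lna(net)$means),
                   error = function(e) round(net$system_size *
                                               net$species$initial))
  }
  n0 <- order_by_species(net, n0)
  if (!all_mass_action(net))
    stop("ssa_moments requires all-mass-action rate laws; use ",
         "gillespie_direct() + stationary_moments() for general kinetics")
  set.seed(seed)
  raw <- ssa_mass_action_cpp(stoichiometry_matrix(net), reactant_matrix(net),
                             vapply(net$reactions,
                                    function(r) net$parameters[[r$rate$constant]],
                                    0),
                             net$system_size, n0, t_end, burn_in,
                             as.integer(n_blocks), record = FALSE,
                             max_record = 0L, max_events)
  K <- nrow(net$species)
  ids <- net$species$id
  bT <- raw$block_time
  ok <- bT > 0
  bM <- raw$block_s1[ok, , drop = FALSE] / bT[ok]
  bC <- array(NA_real_, c(sum(ok), K, K))
  for (b in seq_len(sum(ok))) {
    S2 <- matrix(raw$block_s2[which(ok)[b], ], K, K) / bT[ok][b]
    bC[b, , ] <- S2 - tcrossprod(bM[b, ])
  }
  W <- sum(bT)
  mu <- colSums(raw$block_s1) / W
  S2 <- matrix(colSums(raw$block_s2), K, K) / W
  covm <- S2 - tcrossprod(mu)
  covm <- (covm + t(covm)) / 2
  nb <- sum(ok)
  se_cov <- apply(bC, c(2, 3), stats::sd) / sqrt(nb)
  se_mean <- apply(bM, 2, stats::sd) / sqrt(nb)
  dimnames(covm) <- list(ids, ids)
  dimnames(se_cov) <- list(ids, ids)
  structure(list(mean = stats::setNames(mu, ids), cov = covm,
                 se_cov = se_cov, se_mean = stats::setNames(se_mean, ids),
                 window = W, burn_in = burn_in, n_blocks = nb,
                 n_events = raw$n_events, absorbed = raw$absorbed,
                 seed = seed),
            class = "moment_estimate")
}

#' @export
print.moment_estimate <- function(x, ...) {
  cat("<moment_estimate> window ", format(x$window), " time units\n", sep = "")
  print(round(rbind(mean = x$mean), 3))
  cat("covariance:\n"); print(round(x$cov, 3))
  invisible(x)
}

#' Compare LNA covariances with a long SSA run
#'
#' Computes the LNA particle-number covariance and an ergodic SSA estimate
#' on the same network, reporting every entry side by side with its relative
#' difference and the SSA batch-means standard error.
#'
#' @inheritParams ssa_moments
#' @return A tibble (class `lna_ssa_comparison`) with columns `species_i`,
#'   `species_j`, `lna`, `ssa`, `se_ssa`, `rel_diff`; the LNA result and the
#'   moment estimate are attached as attributes `lna` and `ssa`.
#' @export
compare_lna_ssa <- function(net, t_end, burn_in = 0.1 * t_end, seed = 1L,
                            n_blocks = 20L) {
  res <- lna(net)
  mom <- ssa_moments(net, t_end = t_end, burn_in = burn_in,
                     n0 = round(res$means), seed = seed, n_blocks = n_blocks)
  ids <- net$species$id
  pairs <- expand.grid(j = seq_along(ids), i = seq_along(ids))[, 2:1]
  pairs <- pairs[pairs$i <= pairs$j, ]
  out <- tibble::tibble(
    species_i = ids[pairs$i], species_j = ids[pairs$j],
    lna = res$C[cbind(pairs$i, pairs$j)],
    ssa = mom$cov[cbind(pairs$i, pairs$j)],
    se_ssa = mom$se_cov[cbind(pairs$i, pairs$j)])
  out$rel_diff <- (out$ssa - out$lna) / ifelse(abs(out$lna) > 0, abs(out$lna), 1)
  attr(out, "lna") <- res
  attr(out, "ssa") <- mom
  class(out) <- c("lna_ssa_comparison", class(out))
  out
}
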