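# conservation: exact detection of conserved moieties (integer left null
# vectors of the stoichiometry matrix), choice of independent species, and
# the link matrix connecting the reduced and full systems.
#
# The elimination is fraction-free (integer, Bareiss-style), so a returned
# moiety vector g satisfies g %*% N == 0 exactly -- a hard requirement:
# an inexact relation leaves the drift matrix singular and the Lyapunov
# solution non-unique.

#' Find conservation relations of a stoichiometry matrix
#'
#' Scans species in declared order, retaining a species as independent while
#' its stoichiometry row increases the rank; each remaining (dependent)
#' species `j` yields an integer moiety vector `g` with `g %*% N = 0` and
#' `g[j] > 0`, i.e. a conserved total `sum(g * n)`.
#'
#' @param N Integer stoichiometry matrix (species x reactions), e.g. from
#'   [stoichiometry_matrix()].
#' @return A list with `independent`/`dependent` (row indices), and
#'   `relations`: one entry per dependent species with the integer moiety
#'   vector `g`, the dependent index, and rational coefficients `alpha` over
#'   the independent species such that
#'   `n_j = constant + sum(alpha * n_independent)`.
#' @export
#' @examples
#' N <- stoichiometry_matrix(michaelis_menten())
#' find_conservation_relations(N)
find_conservation_relations <- function(N) {
  N <- as.matrix(N)
  storage.mode(N) <- "double"
  stopifnot(all(N == round(N)))
  khat <- nrow(N)
  pivots <- list()   # each: list(col, row = integer augmented row)
  independent <- integer(0)
  relations <- list()
  for (i in seq_len(khat)) {
    v <- c(N[i, ], numeric(khat))
    v[ncol(N) + i] <- 1
    for (p in pivots) {
      if (v[p$col] != 0) {
        v <- v * p$row[p$col] - p$row * v[p$col]
        g <- gcd_vec(v)
        if (g > 1) v <- v / g
      }
    }
    lead <- which(v[seq_len(ncol(N))] != 0)
    if (length(lead)) {
      pivots[[length(pivots) + 1L]] <- list(col = lead[1L], row = v)
      independent <- c(independent, i)
    } else {
      g <- unname(v[ncol(N) + seq_len(khat)])
      if (g[i] < 0) g <- -g
      relations[[length(relations) + 1L]] <- list(
        dependent = i,
        g = g,
        alpha_full = -g / g[i]  # over all species; support is on independents
      )
    }
  }
  dependent <- vapply(relations, `[[`, 0, "dependent")
  relations <- lapply(relations, function(rel) {
    rel$alpha <- rel$alpha_full[independent]
    rel$alpha_full <- NULL
    rel
  })
  list(independent = independent, dependent = dependent, relations = relations)
}

gcd_vec <- function(v) {
  v <- abs(v[v != 0])
  if (!length(v)) return(1)
  g <- v[1]
  for (x in v[-1]) g <- gcd2(g, x)
  g
}
gcd2 <- function(a, b) {
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Link matrix of a reduced system
#'
#' Builds `L = rbind(I_K, L0)` in the independent-first species ordering;
#' row `j` of `L0` holds the coefficients `alpha_jk` expressing dependent
#' species `j` in terms of the independent species.
#'
#' @param relations Result of [find_conservation_relations()].
#' @return Matrix of dimension Khat x K.
#' @export
link_matrix <- function(relations) {
  K <- length(relations$independent)
  L0 <- do.call(rbind, c(lapply(relations$relations, `[[`, "alpha"),
                         list(matrix(0, 0, K))))
  rbind(diag(K), L0)
}

#' Reduce a network to its independent species
#'
#' Detects conserved moieties, selects independent species (first-come in
#' declared order), computes conservation constants from the current initial
#' densities, and assembles the link matrix and reduced stoichiometry.
#'
#' @param net An irreversible [reaction_network()].
#' @return A `reduced_system` with elements `net`, `independent`/`dependent`
#'   (original indices), `K`, `Khat`, `Lambda`, `moieties` (Lambda x Khat
#'   integer matrix of left-null vectors), `alpha` (Lambda x K), `constants`
#'   (density-scale constants of the relations), `L` (Khat x K link matrix in
#'   original species order) and `N_red` (K x M reduced stoichiometry).
#' @export
reduce_network <- function(net) {
  stop_if_reversible(net)
  N <- stoichiometry_matrix(net)
  rel <- find_conservation_relations(N)
  K <- length(rel$independent)
  Khat <- nrow(N)
  Lambda <- length(rel$dependent)
  alpha <- do.call(rbind, c(lapply(rel$relations, `[[`, "alpha"),
                            list(matrix(0, 0, K))))
  moieties <- do.call(rbind, c(lapply(rel$relations, `[[`, "g"),
                               list(matrix(0, 0, Khat))))
  x0 <- stats::setNames(net$species$initial, net$species$id)
  # density-scale constants: x_dep = b + alpha %*% x_ind along any trajectory
  b <- if (Lambda) as.numeric(x0[rel$dependent] - alpha %*% x0[rel$independent])
       else numeric(0)
  # link matrix with rows in ORIGINAL species order
  L <- matrix(0, Khat, K,
              dimnames = list(net$species$id, net$species$id[rel$independent]))
  L[rel$independent, ] <- diag(K)
  if (Lambda) L[rel$dependent, ] <- alpha
  N_red <- N[rel$independent, , drop = FALSE]
  stopifnot(qr(N_red)$rank == K)
  structure(list(net = net, independent = rel$independent,
                 dependent = rel$dependent, K = K, Khat = Khat,
                 Lambda = Lambda, moieties = moieties, alpha = alpha,
                 constants = b, L = L, N_red = N_red,
                 fast = compile_rate_calls(net)),
            class = "reduced_system")
}

#' @export
print.reduced_system <- function(x, ...) {
  cat("<reduced_system> ", x$Khat, " species -> ", x$K,
      " independent (", x$Lambda, " conservation relation",
      if (x$Lambda != 1) "s", ")\n", sep = "")
  cat(reduction_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable summary of the conserved sums
#'
#' @param rs A [reduce_network()] result.
#' @return Character vector, one conserved sum per line, with its value at
#'   the network's initial state (in particle numbers).
#' @export
reduction_report <- function(rs) {
  if (rs$Lambda == 0) return("no conservation relations")
  ids <- rs$net$species$id
  x0 <- rs$net$species$initial
  omega <- rs$net$system_size
  vapply(seq_len(rs$Lambda), function(l) {
    g <- rs$moieties[l, ]
    terms <- ifelse(abs(g[g != 0]) == 1, paste0("[", ids[g != 0], "]"),
                    paste0(abs(g[g != 0]), " [", ids[g != 0], "]"))
    signs <- ifelse(g[g != 0] > 0, " + ", " - ")
    signs[1] <- ifelse(g[g != 0][1] > 0, "", "-")
    paste0(paste0(signs, terms, collapse = ""), " = ",
           format(sum(g * x0) * omega), " particles")
  }, character(1))
}

# Pre-compose single `c(...)` calls evaluating all rates / all non-zero
# Jacobian entries in one eval(): the steady-state search and the ODE
# fallback call these thousands of times per closed-loop evaluation.
compile_rate_calls <- function(net) {
  ids <- net$species$id
  exprs <- lapply(net$reactions, function(r) rate_law_expr(r$rate, r$reactants))
  rate_call <- as.call(c(quote(c), exprs))
  jexprs <- list()
  jrow <- integer(0); jcol <- integer(0)
  for (m in seq_along(exprs)) {
    for (sp in intersect(expr_symbols(exprs[[m]]), ids)) {
      jexprs[[length(jexprs) + 1L]] <- diff_expr(exprs[[m]], sp)
      jrow <- c(jrow, m); jcol <- c(jcol, match(sp, ids))
    }
  }
  list(rate_call = rate_call,
       jac_call = as.call(c(quote(c), jexprs)),
       jac_index = cbind(jrow, jcol),
       M = length(exprs), ids = ids)
}

rate_env <- function(rs, params = rs$net$parameters)
  list2env(as.list(params), parent = baseenv())

set_species_env <- function(env, ids, x) {
  for (i in seq_along(ids)) assign(ids[i], x[[i]], envir = env)
  invisible(env)
}

# all reaction rates at full density vector x (no validation: internal)
rates_fast <- function(rs, x_full, env) {
  set_species_env(env, rs$fast$ids, x_full)
  eval(rs$fast$rate_call, env)
}

# M x Khat rate Jacobian at full density vector x (internal)
rate_jacobian_fast <- function(rs, x_full, env) {
  set_species_env(env, rs$fast$ids, x_full)
  J <- matrix(0, rs$fast$M, rs$Khat)
  J[rs$fast$jac_index] <- eval(rs$fast$jac_call, env)
  J
}

# full density vector from independent densities via the conservation relations
full_state <- function(rs, x_ind) {
  x <- numeric(rs$Khat)
  names(x) <- rs$net$species$id
  x[rs$independent] <- x_ind
  if (rs$Lambda)
    x[rs$dependent] <- rs$constants + as.numeric(rs$alpha %*% x_ind)
  x
}

# reduced deterministic drift dx_ind/dt
drift_reduced <- function(rs, x_ind, params = rs$net$parameters) {
  f <- macroscopic_rates(rs$net, full_state(rs, x_ind), params)
  as.numeric(rs$N_red %*% f)
}

# Jacobian of the reduced drift wrt independent densities:
# N_red %*% (df/dx_full) %*% L  (chain rule through the dependents)
drift_jacobian_reduced <- function(rs, x_ind, params = rs$net$parameters) {
  Df <- rate_jacobian(rs$net, full_state(rs, x_ind), params)
  rs$N_red %*% Df %*% rs$L
}
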