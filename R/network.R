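# model_core: single-compartment stochastic reaction networks.
#
# A network holds an ordered species list (number densities x_i = n_i / Omega),
# irreversible (after splitting) reactions with kinetic rate laws, named
# parameters and a scalar system size Omega converting densities to particle
# numbers, n = Omega * x. For models parameterised in molar units Omega
# absorbs N_A * V and the unit factor.

#' Declare a reaction
#'
#' @param id Unique reaction identifier.
#' @param reactants,products Named integer vectors of stoichiometries,
#'   e.g. `c(S = 1, E = 1)`; an empty vector (`NULL`) denotes a source/sink.
#' @param rate A [mass_action()] or [rate_expr()] rate law (a character
#'   string is parsed as an expression law).
#' @param reversible Logical; reversible reactions must carry a rate law of
#'   the form `forward - backward` and be split with [split_reversible()]
#'   before any LNA computation.
#' @return A `reaction` object.
#' @export
#' @examples
#' reaction("bind", c(S = 1, E = 1), c(SE = 1), mass_action("k2"))
reaction <- function(id, reactants = NULL, products = NULL, rate,
                     reversible = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  reactants <- check_stoich(reactants, id, "reactants")
  products <- check_stoich(products, id, "products")
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction `", id, "`: at least one of reactants/products must be non-empty")
  structure(list(id = id, reactants = reactants, products = products,
                 rate = as_rate_law(rate), reversible = isTRUE(reversible)),
            class = "reaction")
}

check_stoich <- function(s, id, what) {
  if (is.null(s)) return(stats::setNames(numeric(0), character(0)))
  if (!is.numeric(s) || is.null(names(s)) || any(!nzchar(names(s))))
    stop("reaction `", id, "`: ", what, " must be a named numeric vector")
  if (any(s < 0) || any(s != round(s)))
    stop("reaction `", id, "`: ", what, " stoichiometries must be non-negative integers")
  # collapse duplicated species entries
  tapply_sum <- tapply(s, names(s), sum)
  stats::setNames(as.numeric(tapply_sum), names(tapply_sum))
}

#' Build a reaction network
#'
#' Validates a model description: species ids must be unique, every symbol in
#' a rate law must be a declared species or parameter, and the system size
#' must be positive.
#'
#' @param species A data frame with columns `id`, `initial` (initial number
#'   density, non-negative) and optionally `name` (free-text), in the order
#'   that defines the species indexing.
#' @param reactions A list of [reaction()] objects.
#' @param parameters Named numeric vector (or list) of kinetic parameters.
#' @param system_size Positive scalar Omega; particle numbers are
#'   `n = Omega * x`.
#' @param name Optional model name.
#' @return A `reaction_network` object.
#' @export
#' @examples
#' net <- reaction_network(
#'   species = data.frame(id = "X", initial = 0),
#'   reactions = list(
#'     reaction("in", NULL, c(X = 1), rate_expr("k")),
#'     reaction("out", c(X = 1), NULL, rate_expr("d * X"))
#'   ),
#'   parameters = c(k = 5, d = 0.5), system_size = 10
#' )
#' net
reaction_network <- function(species, reactions, parameters = numeric(),
                             system_size = 1, name = NULL) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  if (nrow(species) == 0L) stop("network must declare at least one species")
  if (!all(c("id", "initial") %in% names(species)))
    stop("`species` needs columns `id` and `initial`")
  if (!"name" %in% names(species)) species$name <- species$id
  species <- species[, c("id", "name", "initial")]
  if (anyDuplicated(species$id))
    stop("duplicate species ids: ",
         paste(unique(species$id[duplicated(species$id)]), collapse = ", "))
  if (any(species$initial < 0)) stop("initial densities must be >= 0")

  parameters <- unlist(parameters)
  if (length(parameters) &&
      (is.null(names(parameters)) || anyDuplicated(names(parameters))))
    stop("parameters must be uniquely named")
  if (!is.numeric(system_size) || length(system_size) != 1L ||
      !is.finite(system_size) || system_size <= 0)
    stop("system_size (Omega) must be a positive finite scalar")

  stopifnot(is.list(reactions), length(reactions) > 0L)
  reactions <- lapply(reactions, function(r) {
    if (!inherits(r, "reaction")) stop("`reactions` must be reaction() objects")
    r
  })
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction ids: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  net <- structure(list(species = species, reactions = reactions,
                        parameters = parameters, system_size = system_size,
                        name = name %||% "network"),
                   class = "reaction_network")
  validate_symbols(net)
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_symbols <- function(net) {
  known <- c(net$species$id, names(net$parameters))
  for (r in net$reactions) {
    for (sp in c(names(r$reactants), names(r$products)))
      if (!sp %in% net$species$id)
        stop("reaction `", r$id, "` references undeclared species `", sp, "`")
    syms <- if (r$rate$kind == "mass_action") r$rate$constant else
      expr_symbols(r$rate$expr)
    bad <- setdiff(syms, known)
    if (length(bad))
      stop("reaction `", r$id, "` rate law references undeclared symbol",
           if (length(bad) > 1) "s" else "", " `",
           paste(bad, collapse = "`, `"), "`")
  }
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", x$name, ": ", nrow(x$species), " species, ",
      length(x$reactions), " reactions, Omega = ",
      format(x$system_size), "\n", sep = "")
  for (r in x$reactions) {
    lhs <- side_string(r$reactants)
    rhs <- side_string(r$products)
    arrow <- if (r$reversible) "<->" else "->"
    law <- if (r$rate$kind == "mass_action")
      paste0("mass action (", r$rate$constant, ")") else deparse1(r$rate$expr)
    cat("  ", format(r$id, width = 8), lhs, arrow, rhs, "  [", law, "]\n")
  }
  invisible(x)
}

side_string <- function(s) {
  if (length(s) == 0L) return("0")
  paste(ifelse(s == 1, names(s), paste0(s, " ", names(s))), collapse = " + ")
}

#' Update parameters or initial densities of a network
#'
#' @param net A [reaction_network()].
#' @param ... Named parameter values to set (must already be declared).
#' @param initial Optional named vector of initial densities to update.
#' @return The modified network.
#' @export
set_parameters <- function(net, ..., initial = NULL) {
  stopifnot(inherits(net, "reaction_network"))
  upd <- unlist(list(...))
  if (length(upd)) {
    bad <- setdiff(names(upd), names(net$parameters))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    net$parameters[names(upd)] <- upd
  }
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), net$species$id)
    if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
    net$species$initial[match(names(initial), net$species$id)] <- initial
  }
  net
}

#' Split reversible reactions into irreversible pairs
#'
#' A reversible reaction with a rate law of the syntactic form
#' `forward - backward` is replaced by the forward reaction (rate `forward`)
#' and its reverse (rate `backward`). The deterministic equations are
#' unchanged; the stochastic description requires each direction separately.
#' Laws not in that form cannot be split automatically and raise an error.
#'
#' @param net A [reaction_network()].
#' @return A network in which every reaction is irreversible; networks with
#'   no reversible reactions are returned unchanged.
#' @export
split_reversible <- function(net) {
  stopifnot(inherits(net, "reaction_network"))
  if (!any(vapply(net$reactions, `[[`, TRUE, "reversible"))) return(net)
  out <- list()
  for (r in net$reactions) {
    if (!r$reversible) {
      out[[length(out) + 1L]] <- r
      next
    }
    if (r$rate$kind != "expression")
      stop("reversible reaction `", r$id,
           "`: mass-action laws carry a single constant; declare the net rate ",
           "as an expression `forward - backward` or split manually")
    parts <- split_difference(r$rate$expr)
    if (is.null(parts))
      stop("reversible reaction `", r$id, "`: rate law is not of the form ",
           "`forward - backward`; split it manually into two irreversible reactions")
    out[[length(out) + 1L]] <- reaction(paste0(r$id, "_fwd"), r$reactants,
                                        r$products, rate_expr(parts$forward))
    out[[length(out) + 1L]] <- reaction(paste0(r$id, "_rev"), r$products,
                                        r$reactants, rate_expr(parts$backward))
  }
  net$reactions <- out
  validate_symbols(net)
  net
}

stop_if_reversible <- function(net) {
  rev <- vapply(net$reactions, `[[`, TRUE, "reversible")
  if (any(rev))
    stop("network contains reversible reactions (",
         paste(vapply(net$reactions[rev], `[[`, "", "id"), collapse = ", "),
         "); run split_reversible() first")
  invisible(net)
}

#' Stoichiometry matrix
#'
#' @param net An irreversible [reaction_network()].
#' @return Integer matrix `N` with `N[i, mu] = p_imu - r_imu`, species in
#'   declared order by row, reactions by column.
#' @export
stoichiometry_matrix <- function(net) {
  stop_if_reversible(net)
  ids <- net$species$id
  N <- matrix(0L, nrow(net$species), length(net$reactions),
              dimnames = list(ids, vapply(net$reactions, `[[`, "", "id")))
  for (m in seq_along(net$reactions)) {
    r <- net$reactions[[m]]
    N[names(r$reactants), m] <- N[names(r$reactants), m] - as.integer(r$reactants)
    N[names(r$products), m] <- N[names(r$products), m] + as.integer(r$products)
  }
  N
}

#' Macroscopic reaction rates
#'
#' Evaluates the kinetic functions `f_mu(x)` at a vector of number densities.
#'
#' @param net An irreversible [reaction_network()].
#' @param x Density vector in declared species order (named vectors are
#'   reordered by name). Small negative values (>= -1e-12, solver overshoot)
#'   are clipped to zero.
#' @param params Parameter values; defaults to the network's.
#' @return Numeric vector of length M with the rate of each reaction.
#' @export
macroscopic_rates <- function(net, x, params = net$parameters) {
  stop_if_reversible(net)
  x <- order_by_species(net, x)
  if (any(!is.finite(x))) stop("non-finite density")
  if (any(x < -1e-12)) stop("negative density")
  x[x < 0] <- 0
  env <- c(as.list(x), as.list(params))
  f <- vapply(net$reactions, function(r) {
    v <- eval_expr(rate_law_expr(r$rate, r$reactants), env)
    if (!is.finite(v))
      stop("rate law of reaction `", r$id, "` is not finite at the given state ",
           "(division by zero in a saturating term?)")
    v
  }, numeric(1))
  names(f) <- vapply(net$reactions, `[[`, "", "id")
  f
}

order_by_species <- function(net, x) {
  ids <- net$species$id
  if (!is.null(names(x))) {
    if (!setequal(names(x), ids))
      stop("state vector names do not match the species ids")
    x <- x[ids]
  } else if (length(x) != length(ids)) {
    stop("state vector has length ", length(x), ", expected ", length(ids))
  }
  stats::setNames(as.numeric(x), ids)
}

#' Stochastic propensities
#'
#' Transition rates of the chemical master equation under the density-form
#' identification `T_mu(n) = Omega * f_mu(n / Omega)`.
#'
#' @param net An irreversible [reaction_network()].
#' @param n Non-negative integer particle-number vector.
#' @param params Parameter values; defaults to the network's.
#' @return Numeric propensity vector of length M.
#' @export
propensities <- function(net, n, params = net$parameters) {
  n <- order_by_species(net, n)
  if (any(n < 0)) stop("particle numbers must be non-negative")
  net$system_size * macroscopic_rates(net, n / net$system_size, params)
}

#' Deterministic drift of the full system
#'
#' Right-hand side `N %*% f(x)` of the macroscopic rate equations.
#'
#' @inheritParams macroscopic_rates
#' @return Named vector `dx/dt` over all species.
#' @export
drift <- function(net, x, params = net$parameters) {
  N <- stoichiometry_matrix(net)
  drop(N %*% macroscopic_rates(net, x, params))
}

# M x Khat matrix of analytic partial derivatives dF_mu / dx_i at x
rate_jacobian <- function(net, x, params = net$parameters) {
  x <- order_by_species(net, x)
  x[x < 0 & x >= -1e-12] <- 0
  env <- c(as.list(x), as.list(params))
  ids <- net$species$id
  J <- matrix(0, length(net$reactions), length(ids),
              dimnames = list(vapply(net$reactions, `[[`, "", "id"), ids))
  for (m in seq_along(net$reactions)) {
    e <- rate_law_expr(net$reactions[[m]]$rate, net$reactions[[m]]$reactants)
    for (sp in intersect(expr_symbols(e), ids))
      J[m, sp] <- eval_expr(diff_expr(e, sp), env)
  }
  if (any(!is.finite(J))) {
    bad <- rownames(J)[apply(J, 1, function(r) any(!is.finite(r)))]
    stop("non-finite rate derivative in reaction `", bad[1], "`")
  }
  J
}
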