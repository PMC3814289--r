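# Rate laws are stored as a restricted arithmetic expression tree: R language
# objects limited to numbers, names and the calls + - * / ^ ( ). The
# restriction keeps laws analysable (symbolic differentiation, reversible
# splitting) and safe to evaluate on untrusted model files.

.allowed_calls <- c("+", "-", "*", "/", "^", "(")

#' Declare a mass-action rate law
#'
#' The macroscopic rate is `k * prod(x_i ^ r_i)` where `k` is a named rate
#' constant and `r_i` the reactant stoichiometries of the reaction the law is
#' attached to.
#'
#' @param constant Name of the rate constant (must exist in the network's
#'   parameter list).
#' @return A `rate_law` object of kind `"mass_action"`.
#' @seealso [rate_expr()], [reaction()]
#' @export
#' @examples
#' mass_action("k2")
mass_action <- function(constant) {
  stopifnot(is.character(constant), length(constant) == 1L, nzchar(constant))
  structure(list(kind = "mass_action", constant = constant),
            class = "rate_law")
}

#' Declare an arbitrary kinetic rate law
#'
#' The expression may reference declared species densities and parameters and
#' use `+ - * / ^` and parentheses; this covers mass action,
#' Michaelis-Menten and Hill-with-inhibition kinetics.
#'
#' @param expr A one-line character string, e.g. `"V1 * S / (K1 + S)"`.
#' @return A `rate_law` object of kind `"expression"`.
#' @export
#' @examples
#' rate_expr("V2 * MKKK_P / (K2 + MKKK_P)")
rate_expr <- function(expr) {
  if (is.character(expr)) {
    stopifnot(length(expr) == 1L)
    expr <- str2lang(expr)
  }
  check_expr_syntax(expr)
  structure(list(kind = "expression", expr = expr), class = "rate_law")
}

as_rate_law <- function(x) {
  if (inherits(x, "rate_law")) return(x)
  if (is.character(x) || is.language(x) || is.numeric(x)) return(rate_expr(x))
  stop("cannot interpret rate law of class ", paste(class(x), collapse = "/"))
}

#' @export
print.rate_law <- function(x, ...) {
  if (x$kind == "mass_action") {
    cat("<rate law> mass action, constant ", x$constant, "\n", sep = "")
  } else {
    cat("<rate law> ", deparse1(x$expr), "\n", sep = "")
  }
  invisible(x)
}

# walk the expression tree rejecting anything outside the arithmetic subset
check_expr_syntax <- function(e) {
  if (is.numeric(e) || is.name(e)) return(invisible(TRUE))
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (!op %in% .allowed_calls)
      stop("unsupported operation in rate law: `", op,
           "` (only + - * / ^ and parentheses are allowed)")
    for (i in seq_along(e)[-1L]) check_expr_syntax(e[[i]])
    return(invisible(TRUE))
  }
  stop("unsupported token in rate law: ", deparse1(e))
}

expr_symbols <- function(e) {
  if (is.name(e)) return(as.character(e))
  if (is.call(e)) return(unique(unlist(lapply(as.list(e)[-1L], expr_symbols))))
  character()
}

# rate-law expression for symbolic work; mass action is expanded to its
# monomial over the reactant stoichiometry
rate_law_expr <- function(law, reactants) {
  if (law$kind == "expression") return(law$expr)
  e <- as.name(law$constant)
  for (sp in names(reactants)) {
    r <- reactants[[sp]]
    if (r == 0) next
    term <- if (r == 1) as.name(sp) else call("^", as.name(sp), r)
    e <- call("*", e, term)
  }
  e
}

# split `a - b` at top level (descending through parentheses) into the
# forward and backward parts of a reversible law; NULL if not of that form
split_difference <- function(e) {
  while (is.call(e) && identical(e[[1L]], as.name("("))) e <- e[[2L]]
  if (is.call(e) && identical(e[[1L]], as.name("-")) && length(e) == 3L)
    return(list(forward = e[[2L]], backward = e[[3L]]))
  NULL
}

# d(expr)/d(sym) via stats::D; the arithmetic subset is fully supported there
diff_expr <- function(e, sym) stats::D(e, sym)

eval_expr <- function(e, env_list) {
  eval(e, envir = env_list, enclos = baseenv())
}
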