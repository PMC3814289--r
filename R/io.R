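# cli_io: model readers/writers. The native format is structured YAML with
# sections `species`, `reactions`, `parameters`, `system_size`; it is the
# source of truth. SBML import is a convenience subset: single compartment,
# explicit kinetic laws, irreversible reactions (reversible models are
# rejected with an instruction to split, multi-compartment models are
# rejected outright).

#' Write a network to the native YAML model format
#'
#' @param net A [reaction_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "reaction_network"))
  doc <- list(
    name = net$name,
    system_size = net$system_size,
    species = lapply(seq_len(nrow(net$species)), function(i)
      list(id = net$species$id[i], name = net$species$name[i],
           initial = net$species$initial[i])),
    parameters = as.list(net$parameters),
    reactions = lapply(net$reactions, function(r) {
      out <- list(id = r$id)
      if (length(r$reactants)) out$reactants <- as.list(r$reactants)
      if (length(r$products)) out$products <- as.list(r$products)
      out$rate <- if (r$rate$kind == "mass_action")
        list(mass_action = r$rate$constant) else deparse1(r$rate$expr)
      if (r$reversible) out$reversible <- TRUE
      out
    }))
  writeLines(yaml::as.yaml(doc, precision = 15), path)
  invisible(path)
}

#' Read a network from the native YAML model format
#'
#' @param path Model file.
#' @return A validated [reaction_network()].
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse model file ", path, ": ", conditionMessage(e)))
  for (fld in c("species", "reactions", "system_size"))
    if (is.null(doc[[fld]])) stop("model file misses section `", fld, "`")
  species <- do.call(rbind, lapply(doc$species, function(s)
    data.frame(id = s$id, name = s$name %||% s$id,
               initial = as.numeric(s$initial))))
  reactions <- lapply(doc$reactions, function(r) {
    rate <- if (is.list(r$rate) && !is.null(r$rate$mass_action))
      mass_action(r$rate$mass_action) else rate_expr(as.character(r$rate))
    reaction(r$id,
             reactants = unlist(r$reactants),
             products = unlist(r$products),
             rate = rate, reversible = isTRUE(r$reversible))
  })
  reaction_network(species, reactions,
                   parameters = unlist(doc$parameters),
                   system_size = as.numeric(doc$system_size),
                   name = doc$name)
}

#' Import a single-compartment SBML model (subset)
#'
#' Supports SBML Level 2/3 core models with exactly one compartment,
#' irreversible reactions and explicit kinetic laws whose MathML uses the
#' arithmetic operators (plus, minus, times, divide, power) over species,
#' parameters and numbers. Kinetic laws are interpreted as macroscopic
#' density rates and species `initialConcentration` as initial densities.
#' Reversible reactions and multi-compartment models are rejected
#' explicitly.
#'
#' @param path SBML file.
#' @param system_size System size Omega of the resulting network; defaults
#'   to the compartment size.
#' @return A [reaction_network()].
#' @export
read_sbml <- function(path, system_size = NULL) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in ", path)

  comps <- xml2::xml_find_all(model, ".//listOfCompartments/compartment")
  if (length(comps) > 1L)
    stop("model has ", length(comps), " compartments; only single-compartment ",
         "models are supported")
  if (is.null(system_size)) {
    sz <- if (length(comps)) xml2::xml_attr(comps[[1]], "size") else NA
    system_size <- if (!is.na(sz)) as.numeric(sz) else 1
  }

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("model declares no species")
  species <- do.call(rbind, lapply(sp_nodes, function(s) {
    conc <- xml2::xml_attr(s, "initialConcentration")
    amt <- xml2::xml_attr(s, "initialAmount")
    init <- if (!is.na(conc)) as.numeric(conc)
            else if (!is.na(amt)) as.numeric(amt) / system_size else 0
    data.frame(id = xml2::xml_attr(s, "id"),
               name = xml2::xml_attr(s, "name") %|na|%
                 xml2::xml_attr(s, "id"),
               initial = init)
  }))

  par_nodes <- xml2::xml_find_all(model, ".//listOfParameters/parameter")
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  if (!length(rx_nodes)) stop("model declares no reactions")
  reactions <- lapply(rx_nodes, function(rx) {
    id <- xml2::xml_attr(rx, "id")
    if (identical(xml2::xml_attr(rx, "reversible"), "true"))
      stop("reaction `", id, "` is reversible; split all reversible ",
           "reactions into irreversible pairs before import")
    side <- function(which) {
      refs <- xml2::xml_find_all(rx, paste0("./", which, "/speciesReference"))
      if (!length(refs)) return(NULL)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry") %|na|% "1")
      stats::setNames(st, xml2::xml_attr(refs, "species"))
    }
    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction `", id, "` has no kinetic law; explicit kinetic laws ",
           "are required")
    # local parameters are hoisted into the global parameter table
    loc <- xml2::xml_find_all(kl, ".//parameter|.//localParameter")
    if (length(loc))
      params <<- c(params, stats::setNames(
        as.numeric(xml2::xml_attr(loc, "value")), xml2::xml_attr(loc, "id")))
    math <- xml2::xml_find_first(kl, "./math/*")
    if (inherits(math, "xml_missing"))
      stop("reaction `", id, "` has an empty kinetic law")
    reaction(id, reactants = side("listOfReactants"),
             products = side("listOfProducts"),
             rate = rate_expr(mathml_to_expr(math)))
  })
  reaction_network(species, reactions, parameters = params,
                   system_size = system_size,
                   name = xml2::xml_attr(model, "id") %|na|% "sbml_model")
}

`%|na|%` <- function(a, b) ifelse(is.na(a), b, a)

# minimal MathML -> R expression converter for the arithmetic subset
mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      nums <- as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1]])
      return(nums[1] * 10^nums[2])
    }
    return(as.numeric(xml2::xml_text(node)))
  }
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], mathml_to_expr)
    fold <- function(sym) Reduce(function(a, b) call(sym, a, b), args)
    switch(op,
      plus = if (length(args) == 0) 0 else fold("+"),
      times = if (length(args) == 0) 1 else fold("*"),
      minus = if (length(args) == 1) call("-", args[[1]]) else fold("-"),
      divide = fold("/"),
      power = fold("^"),
      stop("unsupported MathML operator <", op, "> in kinetic law"))
  } else {
    stop("unsupported MathML element <", nm, "> in kinetic law")
  }
}

#' Write a covariance matrix as labelled TSV
#'
#' Tab-separated with a header row and a leading label column, '.' decimal
#' separator and full floating-point precision (round-trips to machine
#' precision through [read_covariance()]).
#'
#' @param C Square covariance matrix.
#' @param path Output file.
#' @param species_names Row/column labels (defaults to `rownames(C)`).
#' @return `path`, invisibly.
#' @export
write_covariance <- function(C, path, species_names = rownames(C)) {
  stopifnot(is.matrix(C), nrow(C) == ncol(C))
  if (is.null(species_names)) species_names <- paste0("S", seq_len(nrow(C)))
  stopifnot(length(species_names) == nrow(C))
  lines <- c(paste(c("", species_names), collapse = "\t"),
             vapply(seq_len(nrow(C)), function(i)
               paste(c(species_names[i], sprintf("%.17g", C[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a covariance matrix written by [write_covariance()]
#'
#' @param path TSV file.
#' @return Labelled square matrix.
#' @export
read_covariance <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(d)
}
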