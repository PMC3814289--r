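# cli_io: configuration-driven task runner tying the modules into the
# closed-loop workflow. A run configuration (YAML file or list) names a
# model (file or bundled fixture), exactly one task and its options; every
# artifact written embeds the package version, a hash of the configuration
# and the seed, so deterministic tasks reproduce byte-identical numbers.

#' Execute a configured analysis task
#'
#' Tasks: `lna` (covariance matrix TSV + JSON report with A, B,
#' eigenvalues, residuals), `steady-state` (JSON report), `scan` (TSV
#' table), `optimise` (JSON report), `ssa` (trajectory TSV) and `validate`
#' (LNA vs SSA comparison TSV).
#'
#' @param config Path to a YAML configuration or an equivalent named list.
#'   Fields: `model` (file path) or `fixture` (name of a bundled
#'   constructor, e.g. `"michaelis_menten"`, with optional `fixture_args`),
#'   `task`, `seed`, and task blocks `scan`/`optimise`/`ssa` (ranges,
#'   statistic/objective, points, algorithm, t_end, ...).
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the computed result object and the paths
#'   of the written artifacts.
#' @export
run_task <- function(config, out_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  task <- config$task
  if (is.null(task) ||
      !task %in% c("lna", "steady-state", "scan", "optimise", "ssa",
                   "validate"))
    stop("config must name exactly one task out of: lna, steady-state, ",
         "scan, optimise, ssa, validate")
  net <- load_model_config(config)
  seed <- config$seed %||% 1L
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- list(tool = "lnakit",
               version = as.character(utils::packageVersion("lnakit")),
               config_hash = rlang::hash(config), seed = seed)
  paths <- character(0)
  result <- switch(task,
    "lna" = {
      res <- lna(net)
      p1 <- file.path(out_dir, "covariance.tsv")
      write_covariance(res$C, p1)
      p2 <- file.path(out_dir, "lna_report.json")
      jsonlite::write_json(c(meta, list(
        species = net$species$id, means = res$means, A = res$A, B = res$B,
        eigenvalues = list(re = Re(res$steady_state$eigenvalues),
                           im = Im(res$steady_state$eigenvalues)),
        steady_state_residual = res$steady_state$residual,
        lyapunov_residual = res$lyapunov_residual)),
        p2, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
      paths <- c(p1, p2)
      res
    },
    "steady-state" = {
      ss <- find_steady_state(reduce_network(net))
      p <- file.path(out_dir, "steady_state.json")
      jsonlite::write_json(c(meta, list(
        species = net$species$id, densities = ss$x,
        particles = ss$mean_particles, residual = ss$residual,
        eigenvalues = list(re = Re(ss$eigenvalues), im = Im(ss$eigenvalues)),
        stable = ss$stable)), p, digits = NA, auto_unbox = TRUE)
      paths <- p
      ss
    },
    "scan" = {
      sc <- config$scan %||% stop("task `scan` needs a `scan` block")
      ranges <- parse_ranges(sc$ranges)
      res <- scan_statistic(net, parse_statistic(sc), ranges,
                            points = sc$points %||% 26L)
      p <- file.path(out_dir, "scan.tsv")
      utils::write.table(as.data.frame(res), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
                 file.path(out_dir, "scan_meta.json"))
      paths <- c(p, file.path(out_dir, "scan_meta.json"))
      res
    },
    "optimise" = {
      oc <- config$optimise %||% stop("task `optimise` needs an `optimise` block")
      res <- optimise_noise(net, parse_statistic(oc), parse_ranges(oc$ranges),
                            method = oc$algorithm %||% "particle_swarm",
                            seed = seed,
                            swarm_size = oc$swarm_size %||% 50L,
                            max_iter = oc$max_iter %||% 100L)
      p <- file.path(out_dir, "optimisation.json")
      jsonlite::write_json(c(meta, list(
        method = res$method, best_parameters = as.list(res$best_parameters),
        best_value = res$best_value, evaluations = res$evaluation_count,
        infeasible_evaluations = res$n_infeasible,
        termination = res$termination,
        trace = res$trace)), p, digits = NA, auto_unbox = TRUE)
      paths <- p
      res
    },
    "ssa" = {
      sc <- config$ssa %||% stop("task `ssa` needs an `ssa` block")
      tr <- gillespie_direct(net, t_end = sc$t_end %||% 100, seed = seed)
      p <- file.path(out_dir, "trajectory.tsv")
      df <- data.frame(time = tr$times, tr$states, check.names = FALSE)
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
                 file.path(out_dir, "ssa_meta.json"))
      paths <- c(p, file.path(out_dir, "ssa_meta.json"))
      tr
    },
    "validate" = {
      sc <- config$ssa %||% list()
      cmp <- compare_lna_ssa(net, t_end = sc$t_end %||% 1e4, seed = seed)
      p <- file.path(out_dir, "lna_vs_ssa.tsv")
      utils::write.table(as.data.frame(cmp), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE),
                 file.path(out_dir, "validate_meta.json"))
      paths <- c(p, file.path(out_dir, "validate_meta.json"))
      cmp
    })
  invisible(list(result = result, paths = paths, meta = meta))
}

load_model_config <- function(config) {
  if (!is.null(config$model)) {
    net <- read_network(config$model)
  } else if (!is.null(config$fixture)) {
    fixtures <- c("michaelis_menten", "birth_death", "linear_chain",
                  "erk_cascade", "two_branch_cascade")
    if (!config$fixture %in% fixtures)
      stop("unknown fixture `", config$fixture, "`; available: ",
           paste(fixtures, collapse = ", "))
    net <- do.call(config$fixture, config$fixture_args %||% list())
  } else {
    stop("config must give either `model` (a file) or `fixture` (a name)")
  }
  if (!is.null(config$parameters))
    net <- do.call(set_parameters, c(list(net), config$parameters))
  net
}

parse_ranges <- function(ranges) {
  if (is.null(ranges)) stop("missing `ranges`")
  lapply(names(ranges), function(nm)
    param_range(nm, ranges[[nm]][[1]], ranges[[nm]][[2]]))
}

parse_statistic <- function(block) {
  cons <- lapply(block$constraints %||% list(), function(cc)
    constraint(cc$species, min = cc$min %||% 0, max = cc$max %||% Inf,
               relative = isTRUE(cc$relative)))
  if (!is.null(block$maximise))
    return(objective_spec(block$maximise, "maximise", cons))
  if (!is.null(block$minimise))
    return(objective_spec(block$minimise, "minimise", cons))
  if (!is.null(block$statistic))
    return(objective_spec(block$statistic, "maximise", cons))
  stop("block must give `statistic`, `maximise` or `minimise`")
}

#' List the bundled model fixtures
#'
#' @return Character vector of fixture constructor names.
#' @export
list_fixtures <- function() {
  c("michaelis_menten", "birth_death", "linear_chain", "erk_cascade",
    "two_branch_cascade")
}
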