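.config_sections <- c("parameters", "niche", "solver", "experiments",
                      "grids", "cohort", "estimate", "seed")

.default_config <- function() {
  list(
    parameters = list(),         # overrides of hsc_params() defaults
    niche = list(delta = 0, treatment_time = NULL),
    solver = list(step = 0.01, t_end = 280, seed_cells = 100),
    experiments = "simulate",
    grids = list(h = seq(0.25, 3, length.out = 25),
                 rho = seq(0.25, 3, length.out = 25),
                 delta = seq(0, 0.2, length.out = 21)),
    cohort = list(n_young = 5, n_old = 6, young_mean = 10000,
                  fractional_decline = 0.8, cv_young = 0.15, cv_old = 0.15),
    estimate = list(fraction = 0.2, delta = 0),
    seed = 1
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, rejects unknown keys, fills in defaults
#' for everything unset (model parameters default to the healthy reference
#' values), and validates the resulting parameter set and niche schedule.
#' An empty file yields the pure defaults.
#'
#' Recognized top-level sections: `parameters` (any [hsc_params()]
#' argument; `r2` may not be set directly), `niche` (`delta`,
#' `treatment_time`), `solver` (`step`, `t_end`, `seed_cells`),
#' `experiments` (subset of `simulate`, `sweep_competition`, `sweep_niche`,
#' `threshold`, `intervene`, `cohort`, `estimate`, `contour`), `grids`
#' (`h`, `rho`, `delta` vectors), `cohort` ([generate_cohort()] arguments),
#' `estimate` (`fraction`, `delta`), and `seed`.
#'
#' @param path path to a YAML file.
#' @return An object of class `run_config`: the fully materialized
#'   configuration with `params` ([hsc_params()]) and `niche`
#'   ([niche_schedule()]) built and validated.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_run_config(raw)
}

#' Build a run configuration from a list
#'
#' Programmatic equivalent of [read_run_config()].
#'
#' @param overrides named list with any of the recognized sections.
#' @return A `run_config` object.
#' @export
build_run_config <- function(overrides = list()) {
  unknown <- setdiff(names(overrides), .config_sections)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- .default_config()
  for (sec in names(overrides)) {
    if (sec %in% c("experiments", "seed")) {
      cfg[[sec]] <- overrides[[sec]]
    } else {
      extra <- setdiff(names(overrides[[sec]]), names(cfg[[sec]]))
      if (sec == "parameters") {
        valid <- setdiff(names(formals(hsc_params)), character(0))
        extra <- setdiff(names(overrides[[sec]]), valid)
      }
      if (length(extra))
        stop("unknown key(s) in '", sec, "': ",
             paste(extra, collapse = ", "), call. = FALSE)
      cfg[[sec]][names(overrides[[sec]])] <- overrides[[sec]]
    }
  }
  stages <- c("simulate", "sweep_competition", "sweep_niche", "threshold",
              "intervene", "cohort", "estimate", "contour")
  bad <- setdiff(cfg$experiments, stages)
  if (length(bad))
    stop("unknown experiment stage(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg$params <- do.call(hsc_params, cfg$parameters)
  cfg$niche <- niche_schedule(cfg$niche$delta, cfg$niche$treatment_time)
  if (cfg$solver$step <= 0 || cfg$solver$t_end <= 0 ||
      cfg$solver$seed_cells < 0)
    stop("solver settings must be positive (seed_cells >= 0)", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved run configuration
#'
#' Serializes a `run_config` back to YAML with every default materialized,
#' so that `read_run_config(write_run_config(cfg, f))` reproduces `cfg`.
#' Written alongside every pipeline run as the reproducibility echo.
#'
#' @param config a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- list(
    parameters = config$params[setdiff(names(config$params), "r2")],
    niche = list(delta = config$niche$delta,
                 treatment_time = config$niche$treatment_time),
    solver = config$solver,
    experiments = config$experiments,
    grids = lapply(config$grids, as.numeric),
    cohort = config$cohort,
    estimate = config$estimate,
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat("  Stages:", paste(x$experiments, collapse = ", "), "\n")
  cat(sprintf("  Solver: step %g d, t_end %g d, seed_cells %g\n",
              x$solver$step, x$solver$t_end, x$solver$seed_cells))
  cat(sprintf("  Seed: %s\n", x$seed))
  print(x$params)
  print(x$niche)
  invisible(x)
}
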