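.CONFIG_KEYS <- c("component1", "component2", "association", "copula", "tau",
                  "alpha", "two_sided", "power", "allocation", "construction",
                  "method", "reps", "seed", "grid_points")
.COMPONENT_KEYS <- c("shape", "p0", "hr", "observation")

.CONFIG_DEFAULTS <- list(copula = "frank", alpha = 0.025, two_sided = FALSE,
                         power = 0.80, allocation = 0.5,
                         construction = "marginal_ph", method = "gahr",
                         reps = 0L, seed = NULL, grid_points = 1000L)

#' Load and validate a scenario configuration file
#'
#' Reads one design scenario from a YAML (or JSON, a YAML subset) file and
#' validates it completely before any computation: unknown keys are
#' rejected, every constraint violation names the offending key, and all
#' defaults (`copula: frank`, `alpha: 0.025` one-sided, `power: 0.80`,
#' `allocation: 0.5`, `construction: marginal_ph`, `grid_points: 1000`,
#' `reps: 0`) are filled in so the resolved configuration is
#' self-contained.
#'
#' Required keys: `component1` and `component2` (each with `shape`, `p0`,
#' `hr` and optional `observation`), `association` (with `measure` and
#' `value`), and `tau`.
#'
#' @param path Path to the configuration file.
#' @return A list of class `"scenario_config"` with elements `component1`,
#'   `component2` ([component_spec()]), `association`
#'   ([association_spec()]), `family`, `tau`, `params` ([design_params()]),
#'   `construction`, `method`, `reps`, `seed`, `grid_points`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw)) {
    stop("empty configuration; required keys: component1, component2, association, tau",
         call. = FALSE)
  }
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c("component1", "component2", "association", "tau"), names(raw))
  if (length(missing)) {
    stop("missing required key(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  cfg <- modifyList(.CONFIG_DEFAULTS, raw, keep.null = TRUE)

  parse_component <- function(x, key) {
    bad <- setdiff(names(x), .COMPONENT_KEYS)
    if (length(bad)) {
      stop(sprintf("unknown field(s) in %s: %s", key, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    need <- setdiff(c("shape", "p0", "hr"), names(x))
    if (length(need)) {
      stop(sprintf("%s is missing field(s): %s", key, paste(need, collapse = ", ")),
           call. = FALSE)
    }
    tryCatch(
      component_spec(x$shape, x$p0, x$hr,
                     observation = x$observation %||% "cause_specific"),
      error = function(e) stop(sprintf("%s: %s", key, conditionMessage(e)), call. = FALSE))
  }
  comp1 <- parse_component(cfg$component1, "component1")
  comp2 <- parse_component(cfg$component2, "component2")

  a <- cfg$association
  if (!is.list(a) || is.null(a$value)) {
    stop("association must provide 'value' (and optionally 'measure')", call. = FALSE)
  }
  if (!is.null(a$theta)) {
    stop("association: give a rank correlation ('measure'/'value'), not theta",
         call. = FALSE)
  }
  assoc <- tryCatch(association_spec(a$value, a$measure %||% "spearman"),
                    error = function(e) stop("association: ", conditionMessage(e), call. = FALSE))
  family <- match.arg(cfg$copula, c("frank", "clayton", "gumbel"))
  construction <- match.arg(cfg$construction, c("marginal_ph", "cause_specific_ph"))
  method <- match.arg(cfg$method, c("gahr", "nhr"))
  if (!is.numeric(cfg$tau) || cfg$tau <= 0) stop("tau must be positive", call. = FALSE)
  params <- design_params(cfg$alpha, cfg$power, cfg$allocation,
                          two_sided = isTRUE(cfg$two_sided))
  structure(list(component1 = comp1, component2 = comp2, association = assoc,
                 family = family, tau = cfg$tau, params = params,
                 construction = construction, method = method,
                 reps = as.integer(cfg$reps),
                 seed = if (is.null(cfg$seed)) NULL else as.integer(cfg$seed),
                 grid_points = as.integer(cfg$grid_points)),
            class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a scenario configuration file
#'
#' Serialises a `"scenario_config"` back to YAML, including every resolved
#' default, so that [load_config()] on the written file reproduces the
#' configuration exactly.
#'
#' @param config A `"scenario_config"` (from [load_config()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  out <- list(
    component1 = config$component1[c("shape", "p0", "hr", "observation")],
    component2 = config$component2[c("shape", "p0", "hr", "observation")],
    association = list(measure = config$association$measure,
                       value = config$association$value),
    copula = config$family, tau = config$tau,
    alpha = config$params$alpha, two_sided = FALSE,
    power = config$params$power, allocation = config$params$allocation,
    construction = config$construction, method = config$method,
    reps = config$reps, grid_points = config$grid_points)
  if (!is.null(config$seed)) out$seed <- config$seed
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the design pipeline for a loaded configuration
#'
#' Convenience wrapper: [design_scenario()] with every argument taken from
#' a validated `"scenario_config"`, optionally followed by the Monte-Carlo
#' power engine when `reps > 0`.
#'
#' @param config A `"scenario_config"`.
#' @return A `"design_result"`; when `reps > 0` it carries the
#'   `"simulation_result"` in `$simulation`.
#' @export
run_config <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  res <- design_scenario(config$component1, config$component2,
                         config$association, config$family, config$tau,
                         config$params, config$method, config$construction)
  if (config$reps > 0) {
    res$simulation <- empirical_power(res$model, res$n, reps = config$reps,
                                      alpha = config$params$alpha,
                                      allocation = config$params$allocation,
                                      seed = config$seed)
  }
  res
}
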