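#' Scenario grids for the simulation study
#'
#' Builds the factorial grids of design scenarios used to stress the
#' gAHR-based sample-size method, scaled to a unit follow-up time. Both
#' settings cross control-group observation probabilities
#' `p in {0.05, 0.1, 0.3, 0.5}` (cause-specific, both components), hazard
#' ratios `HR in {0.6, 0.8, 0.9}` and Spearman correlations
#' `rho in {0.1, 0.3, 0.5}`, dropping the unrealistic no-censoring pair
#' `p1 = p2 = 0.5`. Setting 1 keeps both margins exponential
#' (405 scenarios); Setting 2 crosses Weibull shapes
#' `beta in {0.5, 1, 2}` excluding the doubly-exponential pair
#' (3240 scenarios).
#'
#' @param setting 1 (exponential margins) or 2 (Weibull margins).
#' @return A data frame with columns `p1`, `p2`, `hr1`, `hr2`, `rho`,
#'   `shape1`, `shape2`, one row per scenario.
#' @export
scenario_grid <- function(setting = 1) {
  stopifnot(setting %in% c(1, 2))
  p <- c(0.05, 0.1, 0.3, 0.5)
  hr <- c(0.6, 0.8, 0.9)
  rho <- c(0.1, 0.3, 0.5)
  shapes <- if (setting == 1) {
    data.frame(shape1 = 1, shape2 = 1)
  } else {
    s <- expand.grid(shape1 = c(0.5, 1, 2), shape2 = c(0.5, 1, 2))
    s[!(s$shape1 == 1 & s$shape2 == 1), , drop = FALSE]
  }
  base <- expand.grid(p1 = p, p2 = p, hr1 = hr, hr2 = hr, rho = rho,
                      KEEP.OUT.ATTRS = FALSE)
  base <- base[!(base$p1 == 0.5 & base$p2 == 0.5), , drop = FALSE]
  out <- merge(base, shapes, by = NULL)
  rownames(out) <- NULL
  out
}

# Build a gahr_model directly from already-solved group-0 scales (used to
# share calibrations across scenarios that differ only in the hazard
# ratios).
.model_from_scales <- function(scales0, shapes, hr, copula, tau,
                               construction = "marginal_ph") {
  model <- structure(
    list(copula = copula, tau = tau, shapes = shapes, scales0 = scales0,
         scales1 = NULL, hr = hr, construction = construction,
         components = list(
           component_spec(shapes[1], 0.5, hr[1]),
           component_spec(shapes[2], 0.5, hr[2]))),
    class = "gahr_model")
  build_group1(model, construction = construction)
}

#' Run the design pipeline (and optionally the power engine) over a grid
#'
#' For every scenario row: converts the rank correlation to the copula
#' parameter, calibrates the control-group scales (calibrations are shared
#' across scenarios that differ only in the hazard ratios), computes the
#' effect summaries, required events and sample size, flags scenarios whose
#' sample size exceeds `max_n` as excluded, and - when `reps > 0` -
#' estimates the empirical power of each non-excluded scenario by
#' simulation.
#'
#' @param grid A data frame as returned by [scenario_grid()] (columns `p1`,
#'   `p2`, `hr1`, `hr2`, `rho`, `shape1`, `shape2`).
#' @param params A [design_params()].
#' @param family Copula family used both for calibration and simulation.
#' @param tau Follow-up horizon (default 1).
#' @param method `"gahr"` or `"nhr"`: effect summary used for sizing.
#' @param reps Simulated trials per scenario (0 = no simulation).
#' @param seed Base seed; each scenario uses the deterministic stream
#'   `seed + row index` so subsets reproduce the full run.
#' @param max_n Exclusion threshold on the total sample size (default
#'   20000).
#' @param construction Group-1 construction, see [build_group1()].
#' @return The grid with appended columns `gahr`, `nhr`, `p_star_avg`,
#'   `events`, `n`, `excluded`, and (when `reps > 0`) `power_hat`, `se`.
#' @export
run_grid <- function(grid, params = design_params(), family = "frank",
                     tau = 1, method = c("gahr", "nhr"), reps = 0,
                     seed = NULL, max_n = 20000,
                     construction = "marginal_ph") {
  method <- match.arg(method)
  needed <- c("p1", "p2", "hr1", "hr2", "rho", "shape1", "shape2")
  stopifnot(all(needed %in% names(grid)))
  m <- nrow(grid)
  cops <- lapply(unique(grid$rho), function(r) association_to_theta(r, family))
  names(cops) <- as.character(unique(grid$rho))
  calib_cache <- new.env(parent = emptyenv())
  get_scales <- function(row, cop) {
    key <- paste(row$p1, row$p2, row$rho, row$shape1, row$shape2)
    if (!exists(key, calib_cache, inherits = FALSE)) {
      sc <- calibrate_group0(component_spec(row$shape1, row$p1),
                             component_spec(row$shape2, row$p2), cop, tau)
      assign(key, sc, calib_cache)
    }
    get(key, calib_cache, inherits = FALSE)
  }
  out <- grid
  out$gahr <- out$nhr <- out$p_star_avg <- NA_real_
  out$events <- out$n <- NA_integer_
  out$excluded <- NA
  if (reps > 0) out$power_hat <- out$se <- NA_real_
  for (i in seq_len(m)) {
    row <- grid[i, ]
    cop <- cops[[as.character(row$rho)]]
    scales0 <- get_scales(row, cop)
    model <- .model_from_scales(scales0, c(row$shape1, row$shape2),
                                c(row$hr1, row$hr2), cop, tau, construction)
    eff <- effect_summary(model)
    s_hr <- if (method == "gahr") eff$gahr else eff$nhr
    out$gahr[i] <- eff$gahr
    out$nhr[i] <- eff$nhr
    out$p_star_avg[i] <- eff$p_star_avg
    if (s_hr >= 1) {
      out$excluded[i] <- TRUE
      next
    }
    out$events[i] <- as.integer(events_required(s_hr, params))
    out$n[i] <- sample_size(s_hr, eff$p_star_avg, params)
    out$excluded[i] <- out$n[i] > max_n
    if (reps > 0 && !out$excluded[i]) {
      sim <- empirical_power(model, out$n[i], reps = reps,
                             alpha = params$alpha,
                             allocation = params$allocation,
                             seed = if (is.null(seed)) NULL else seed + i)
      out$power_hat[i] <- sim$power_hat
      out$se[i] <- sim$se
    }
  }
  out
}

#' Summarise grid power results by design strata
#'
#' Five-number summaries (min, Q1, median, Q3, max) of a grid column within
#' the strata used to profile the method: treatment effect (any component
#' HR = 0.6 / both HR = 0.9 / other), observed proportions (any p = 0.05 /
#' both p >= 0.3 / other), correlation level, and - when shapes vary -
#' shape pattern; plus a global row.
#'
#' @param results A [run_grid()] result (excluded scenarios are dropped).
#' @param value Name of the summarised column (default `"power_hat"`).
#' @return A data frame with columns `stratum`, `scenarios`, `min`, `q1`,
#'   `median`, `q3`, `max`.
#' @export
summarise_grid <- function(results, value = "power_hat") {
  stopifnot(value %in% names(results))
  res <- results[!results$excluded & !is.na(results[[value]]), , drop = FALSE]
  strata <- list(
    "any HR = 0.6"     = res$hr1 == 0.6 | res$hr2 == 0.6,
    "both HR = 0.9"    = res$hr1 == 0.9 & res$hr2 == 0.9,
    "other effects"    = !(res$hr1 == 0.6 | res$hr2 == 0.6) &
                         !(res$hr1 == 0.9 & res$hr2 == 0.9),
    "any p = 0.05"     = res$p1 == 0.05 | res$p2 == 0.05,
    "both p >= 0.3"    = res$p1 >= 0.3 & res$p2 >= 0.3,
    "other proportions" = !(res$p1 == 0.05 | res$p2 == 0.05) &
                          !(res$p1 >= 0.3 & res$p2 >= 0.3),
    "rho = 0.1" = res$rho == 0.1,
    "rho = 0.3" = res$rho == 0.3,
    "rho = 0.5" = res$rho == 0.5
  )
  if (length(unique(paste(res$shape1, res$shape2))) > 1) {
    strata <- c(strata, list(
      "both shapes 0.5" = res$shape1 == 0.5 & res$shape2 == 0.5,
      "both shapes 2"   = res$shape1 == 2 & res$shape2 == 2,
      "unequal shapes"  = res$shape1 != res$shape2
    ))
  }
  strata <- c(strata, list(global = rep(TRUE, nrow(res))))
  rows <- lapply(names(strata), function(nm) {
    x <- res[[value]][strata[[nm]]]
    if (!length(x)) return(NULL)
    data.frame(stratum = nm, scenarios = length(x),
               min = min(x), q1 = unname(quantile(x, 0.25)),
               median = median(x), q3 = unname(quantile(x, 0.75)),
               max = max(x))
  })
  do.call(rbind, rows)
}

#' Sensitivity of the gAHR to the copula family
#'
#' Computes the gAHR for every scenario of the requested settings under
#' each Archimedean family and returns its deciles per family. The
#' calibration is redone per family, since the copula enters the
#' cause-specific probability equations.
#'
#' @param families Copula families to compare.
#' @param settings Which scenario grids to pool (default both).
#' @param tau Follow-up horizon.
#' @param params A [design_params()]; only used when `included_only = TRUE`
#'   to recompute the exclusion flag per family.
#' @param included_only Drop scenarios whose gAHR-based sample size exceeds
#'   `max_n` before taking deciles (default `FALSE`: all grid scenarios).
#' @param max_n Exclusion threshold when `included_only = TRUE`.
#' @param grid Optional custom scenario data frame (as in [run_grid()]);
#'   overrides `settings`.
#' @return A data frame, one row per family, columns `p10` ... `p90`.
#' @export
gahr_copula_table <- function(families = c("frank", "clayton", "gumbel"),
                              settings = c(1, 2), tau = 1,
                              params = design_params(),
                              included_only = FALSE, max_n = 20000,
                              grid = NULL) {
  if (is.null(grid)) grid <- do.call(rbind, lapply(settings, scenario_grid))
  probs <- seq(0.1, 0.9, by = 0.1)
  rows <- lapply(families, function(fam) {
    res <- run_grid(grid, params = params, family = fam, tau = tau)
    vals <- if (included_only) res$gahr[!res$excluded] else res$gahr
    dec <- quantile(vals, probs)
    cbind(data.frame(family = fam),
          as.data.frame(as.list(setNames(dec, paste0("p", probs * 100)))))
  })
  do.call(rbind, rows)
}
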