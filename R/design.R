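#' Design parameters for a logrank-based superiority trial
#'
#' @param alpha One-sided significance level (default 0.025). With
#'   `two_sided = TRUE`, `alpha` is interpreted as a two-sided level and
#'   halved, the usual protocol convention.
#' @param power Target power `1 - beta` (default 0.80).
#' @param allocation Fraction of patients allocated to the new-therapy
#'   group (default 0.5, balanced design).
#' @param two_sided Logical; see `alpha`.
#' @return An object of class `"design_params"`.
#' @export
design_params <- function(alpha = 0.025, power = 0.80, allocation = 0.5,
                          two_sided = FALSE) {
  if (two_sided) alpha <- alpha / 2
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            allocation > 0, allocation < 1)
  structure(list(alpha = alpha, power = power, allocation = allocation),
            class = "design_params")
}

.zsum <- function(params) qnorm(1 - params$alpha) + qnorm(params$power)

# Unrounded Schoenfeld-type event count with gAHR in the hazard-ratio slot.
.events_raw <- function(gahr, params) {
  .zsum(params)^2 / (params$allocation * (1 - params$allocation) * log(gahr)^2)
}

#' Required number of composite events
#'
#' Schoenfeld-type formula with the geometric average hazard ratio in place
#' of the hazard ratio:
#' `e* = (z_alpha + z_beta)^2 / (pi (1 - pi) log(gAHR(tau))^2)`,
#' rounded up to the next integer. For a balanced design the leading factor
#' is 4.
#'
#' @param gahr Effect summary `gAHR(tau)` in `(0, 1)` (the naive summary may
#'   be supplied instead to size by the naive method).
#' @param params A [design_params()].
#' @return Integer number of composite events (both groups).
#' @export
events_required <- function(gahr, params = design_params()) {
  stopifnot(inherits(params, "design_params"), gahr > 0)
  if (gahr >= 1) {
    stop("no superiority effect (gAHR >= 1); required events unbounded", call. = FALSE)
  }
  e <- ceiling(.events_raw(gahr, params))
  if (e > .Machine$integer.max) {
    stop("required events exceed integer range; effect summary too close to 1",
         call. = FALSE)
  }
  as.integer(e)
}

#' Total sample size
#'
#' Converts the (unrounded) required number of events into patients through
#' the average probability of observing the composite event,
#' `n = e* / p*^(a)(tau)`, rounded up to the nearest even integer so that a
#' balanced design has integer arms. The computation uses the unrounded
#' event count; rounding is applied once, at the end.
#'
#' @inheritParams events_required
#' @param p_star_avg Average composite-event probability `p*^(a)(tau)` in
#'   `(0, 1]`.
#' @return Total sample size for both groups (even integer).
#' @export
sample_size <- function(gahr, p_star_avg, params = design_params()) {
  stopifnot(p_star_avg > 0, p_star_avg <= 1)
  if (gahr >= 1) {
    stop("no superiority effect (gAHR >= 1); sample size unbounded", call. = FALSE)
  }
  n_raw <- .events_raw(gahr, params) / p_star_avg
  2L * as.integer(ceiling(n_raw / 2))
}

#' Power of the logrank test at a given sample size
#'
#' Inverts the sample-size formula through the noncentrality parameter
#' `mu*(tau) = sqrt(n pi (1 - pi) p*^(a)(tau)) log(gAHR(tau))`: the one-sided
#' test rejects when `Z* < -z_alpha`, and `Z*` is approximately normal with
#' mean `mu*(tau)` and unit variance, so the power is
#' `Phi(-z_alpha - mu*(tau))`. At `gAHR = 1` this returns `alpha`.
#'
#' @inheritParams sample_size
#' @param n Total sample size (both groups).
#' @param alpha One-sided significance level.
#' @param allocation Fraction allocated to group 1.
#' @return Approximate power, in `(0, 1)`.
#' @export
power_given_n <- function(gahr, p_star_avg, n, alpha = 0.025, allocation = 0.5) {
  stopifnot(n >= 2, gahr > 0, p_star_avg > 0, p_star_avg <= 1)
  mu <- sqrt(n * allocation * (1 - allocation) * p_star_avg) * log(gahr)
  pnorm(-qnorm(1 - alpha) - mu)
}

#' End-to-end design of one composite-endpoint scenario
#'
#' Runs the full analytic pipeline for one parameter set: rank correlation
#' to copula parameter, calibration of the Weibull scales, effect summary
#' (gAHR or the naive averaged hazard ratio), required events and sample
#' size. Deterministic.
#'
#' @param spec1,spec2 [component_spec()] objects.
#' @param assoc An [association_spec()] or a number (Spearman's rho).
#' @param family Copula family (default `"frank"`).
#' @param tau Follow-up horizon (default 1, time-scaled design).
#' @param params A [design_params()].
#' @param method `"gahr"` (default) or `"nhr"`: which effect summary drives
#'   the event/sample-size formulas. Both use the same calibrated
#'   `p*^(a)(tau)`.
#' @param construction Group-1 construction, see [build_group1()].
#' @return A list of class `"design_result"`: `gahr`, `nhr`, `p_star_avg`,
#'   `events`, `n`, `mu_star` (noncentrality at the returned `n`), plus the
#'   calibrated `model`.
#' @examples
#' res <- design_scenario(component_spec(1, 0.3, 0.8),
#'                        component_spec(1, 0.1, 0.6), assoc = 0.3)
#' res$gahr; res$events; res$n
#' @export
design_scenario <- function(spec1, spec2, assoc,
                            family = c("frank", "clayton", "gumbel"),
                            tau = 1, params = design_params(),
                            method = c("gahr", "nhr"),
                            construction = c("marginal_ph", "cause_specific_ph")) {
  family <- match.arg(family)
  method <- match.arg(method)
  construction <- match.arg(construction)
  cop <- association_to_theta(assoc, family)
  model <- calibrate_model(spec1, spec2, cop, tau, construction)
  eff <- effect_summary(model)
  summary_hr <- if (method == "gahr") eff$gahr else eff$nhr
  if (summary_hr >= 1) {
    stop("scenario implies no superiority effect (summary hazard ratio >= 1)",
         call. = FALSE)
  }
  n <- sample_size(summary_hr, eff$p_star_avg, params)
  mu <- sqrt(n * params$allocation * (1 - params$allocation) * eff$p_star_avg) *
    log(summary_hr)
  structure(list(gahr = eff$gahr, nhr = eff$nhr,
                 p_star_avg = eff$p_star_avg,
                 events = events_required(summary_hr, params),
                 n = n, mu_star = mu, method = method,
                 params = params, model = model),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Composite-endpoint design (", x$method, " method)\n", sep = "")
  cat(sprintf("  gAHR(tau)    = %.4f   (naive HR = %.4f)\n", x$gahr, x$nhr))
  cat(sprintf("  p*_avg(tau)  = %.4f\n", x$p_star_avg))
  cat(sprintf("  events e*    = %d\n", x$events))
  cat(sprintf("  sample size  = %d (both groups)\n", x$n))
  cat(sprintf("  mu*(tau)     = %.3f\n", x$mu_star))
  invisible(x)
}
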