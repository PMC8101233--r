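#' Weibull survival, density and hazard
#'
#' Marginal machinery for the component event times. The parameterisation is
#' `S(t) = exp(-(t/scale)^shape)`, so `shape = 1` is the exponential model
#' (constant hazard), `shape > 1` an increasing hazard and `shape < 1` a
#' decreasing hazard. Two Weibull laws with a common shape have proportional
#' hazards with ratio `(scale0/scale1)^shape`.
#'
#' @param t Time(s), `t >= 0`.
#' @param shape,scale Weibull parameters, both `> 0`.
#' @return Survival probability, density or hazard rate at `t`. For
#'   `shape < 1` the hazard diverges as `t -> 0`.
#' @export
weibull_survival <- function(t, shape, scale) {
  stopifnot(all(t >= 0), shape > 0, scale > 0)
  pweibull(t, shape, scale, lower.tail = FALSE)
}

#' @rdname weibull_survival
#' @export
weibull_density <- function(t, shape, scale) {
  stopifnot(all(t >= 0), shape > 0, scale > 0)
  dweibull(t, shape, scale)
}

# CDF computed as -expm1(-(t/b)^beta): 1 - survival cancels to 0 for
# t near the origin, where the sub-density integrands still need F > 0.
.weibull_cdf <- function(t, shape, scale) -expm1(-(t / scale)^shape)

#' @rdname weibull_survival
#' @export
weibull_hazard <- function(t, shape, scale) {
  stopifnot(all(t >= 0), shape > 0, scale > 0)
  (shape / scale) * (t / scale)^(shape - 1)
}
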