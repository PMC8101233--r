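#' Archimedean copula specification
#'
#' Defines the dependence model shared by both treatment groups: one of the
#' three Archimedean families commonly used for bivariate event times, with
#' association parameter `theta`. Only positive dependence is supported,
#' which covers all realistic composite-endpoint scenarios (the components of
#' a composite outcome are positively associated, if at all).
#'
#' Valid parameter ranges are `theta >= 0` for Frank and Clayton (`theta = 0`
#' is the independence limit and is evaluated as the product copula) and
#' `theta >= 1` for Gumbel (`theta = 1` is independence). Very large `theta`
#' is rejected rather than allowed to overflow: Frank is limited to
#' `theta <= 100`, Clayton to `theta <= 50`, Gumbel to `theta <= 50`, far
#' beyond any rank correlation used in trial design.
#'
#' @param family One of `"frank"`, `"clayton"`, `"gumbel"`.
#' @param theta Association parameter (dimensionless).
#' @return An object of class `"copula_spec"`.
#' @examples
#' cop <- copula_spec("clayton", theta = 2)
#' copula_cdf(0.5, 0.5, cop)
#' @export
copula_spec <- function(family = c("frank", "clayton", "gumbel"), theta) {
  family <- match.arg(family)
  stopifnot(is.numeric(theta), length(theta) == 1L, is.finite(theta))
  lims <- switch(family,
    frank   = c(0, 100),
    clayton = c(0, 50),
    gumbel  = c(1, 50)
  )
  if (theta < lims[1] || theta > lims[2]) {
    stop(sprintf("theta = %g outside the supported range [%g, %g] for the %s copula",
                 theta, lims[1], lims[2], family), call. = FALSE)
  }
  structure(list(family = family, theta = theta), class = "copula_spec")
}

#' @export
print.copula_spec <- function(x, ...) {
  cat(sprintf("%s copula, theta = %.6g\n", x$family, x$theta))
  invisible(x)
}

# theta below which Frank/Clayton are evaluated as the independence copula:
# the Frank generator is singular at theta = 0 and both families converge
# smoothly to uv as theta -> 0.
.THETA_INDEP <- 1e-6

.is_indep <- function(spec) {
  switch(spec$family,
    frank   = spec$theta < .THETA_INDEP,
    clayton = spec$theta < .THETA_INDEP,
    gumbel  = spec$theta - 1 < .THETA_INDEP
  )
}

#' Copula distribution function
#'
#' Evaluates `C(u, v; theta)`, the joint probability that both uniform
#' coordinates fall below `(u, v)`. Vectorised over `u` and `v`.
#'
#' @param u,v Numeric vectors in `[0, 1]` (recycled to common length).
#' @param spec A [copula_spec()].
#' @return `C(u, v; theta)`, within the Frechet bounds
#'   `max(u + v - 1, 0) <= C <= min(u, v)`.
#' @export
copula_cdf <- function(u, v, spec) {
  stopifnot(inherits(spec, "copula_spec"))
  stopifnot(all(u >= 0 & u <= 1), all(v >= 0 & v <= 1))
  if (.is_indep(spec)) return(u * v)
  th <- spec$theta
  switch(spec$family,
    frank = {
      # stable via expm1/log1p; all expm1 terms are negative.  For very
      # strong dependence the ratio can round to -1; clamp and enforce the
      # Frechet upper bound.
      r <- pmax(expm1(-th * u) * expm1(-th * v) / expm1(-th), -1 + 1e-300)
      pmin(-log1p(r) / th, pmin(u, v))
    },
    clayton = {
      # boundary u or v = 0 gives A = Inf -> C = 0; handled by the limit
      a <- u^(-th) + v^(-th) - 1
      out <- a^(-1 / th)
      out[u == 0 | v == 0] <- 0
      out
    },
    gumbel = {
      out <- exp(-((-log(u))^th + (-log(v))^th)^(1 / th))
      out[u == 0 | v == 0] <- 0
      out
    }
  )
}

#' Copula density
#'
#' The mixed second derivative of [copula_cdf()], evaluated in log scale
#' internally so that strongly dependent Frank copulas do not overflow.
#'
#' @inheritParams copula_cdf
#' @return The copula density `c(u, v; theta) >= 0`.
#' @export
copula_density <- function(u, v, spec) {
  stopifnot(inherits(spec, "copula_spec"))
  stopifnot(all(u > 0 & u < 1), all(v > 0 & v < 1))
  if (.is_indep(spec)) return(rep_len(1, length(u * v)))
  th <- spec$theta
  switch(spec$family,
    frank = {
      # c = th (1-e^-th) e^{-th(u+v)} / D^2,
      # D = (1-e^-th) - (1-e^{-th u})(1-e^{-th v})
      d <- (-expm1(-th)) - expm1(-th * u) * expm1(-th * v)
      exp(log(th) + log(-expm1(-th)) - th * (u + v) - 2 * log(d))
    },
    clayton = {
      la <- log(u^(-th) + v^(-th) - 1)
      exp(log1p(th) - (th + 1) * (log(u) + log(v)) - (2 + 1 / th) * la)
    },
    gumbel = {
      x <- (-log(u))^th
      y <- (-log(v))^th
      s <- x + y
      exp(-s^(1 / th)) * s^(2 / th - 2) * ((-log(u)) * (-log(v)))^(th - 1) /
        (u * v) * (1 + (th - 1) * s^(-1 / th))
    }
  )
}

#' Conditional copula distribution (partial derivative in u)
#'
#' `dC/du (u, v)`, which equals `P(V <= v | U = u)`. This is the central
#' primitive of the package: applied to the two marginal survival functions
#' it yields the cause-specific sub-densities of the composite endpoint, and
#' its inverse in `v` drives copula sampling by conditional inversion.
#'
#' All three families are exchangeable, so the partial derivative in `v` is
#' `copula_partial_u(v, u, spec)`.
#'
#' @inheritParams copula_cdf
#' @return Values in `[0, 1]`, nondecreasing in `v`.
#' @export
copula_partial_u <- function(u, v, spec) {
  stopifnot(inherits(spec, "copula_spec"))
  stopifnot(all(u > 0 & u <= 1), all(v >= 0 & v <= 1))
  if (.is_indep(spec)) return(rep_len(1, length(u)) * v)
  th <- spec$theta
  switch(spec$family,
    frank = {
      exp(-th * u) * expm1(-th * v) /
        (expm1(-th) + expm1(-th * u) * expm1(-th * v))
    },
    clayton = {
      # u^(-th-1) overflows for extreme conditioning values; the limit of
      # the conditional distribution as u -> 0 is 1 (clustered lower tail)
      uc <- pmax(u, 1e-30)
      a <- uc^(-th) + v^(-th) - 1
      out <- uc^(-th - 1) * a^(-(1 + 1 / th))
      out[u < 1e-30] <- 1
      out[v == 0] <- 0
      out
    },
    gumbel = {
      # nudge off the corners: the formula is 0/0 at u = 1 or v = 1, but
      # its limit along any interior path is recovered at 1 - 1e-16
      uc <- pmin(pmax(u, 1e-300), 1 - 1e-16)
      vc <- pmin(pmax(v, 1e-300), 1 - 1e-16)
      x <- (-log(uc))^th
      y <- (-log(vc))^th
      s <- x + y
      out <- exp(-s^(1 / th)) * s^(1 / th - 1) * (-log(uc))^(th - 1) / uc
      out[v == 0] <- 0
      out[v == 1] <- 1
      out
    }
  )
}

#' Association measure specification
#'
#' A rank-correlation target used to pin down the copula parameter: either
#' Spearman's rho or Kendall's tau, assumed identical in both treatment
#' groups. Only positive association in `(0, 1)` is supported.
#'
#' @param value Correlation value, strictly between 0 and 1.
#' @param measure `"spearman"` (default) or `"kendall"`.
#' @return An object of class `"association_spec"`.
#' @export
association_spec <- function(value, measure = c("spearman", "kendall")) {
  measure <- match.arg(measure)
  stopifnot(is.numeric(value), length(value) == 1L)
  if (!is.finite(value) || value <= 0 || value >= 1) {
    stop("association value must lie strictly between 0 and 1 (positive dependence only)",
         call. = FALSE)
  }
  structure(list(measure = measure, value = value), class = "association_spec")
}

# Spearman's rho of a copula: rho = 12 int int C(u,v) du dv - 3, evaluated
# by tensor-product Gauss-Legendre quadrature (no closed form for
# Frank/Gumbel).
.spearman_from_spec <- function(spec, n_nodes = 64) {
  g <- gl01(n_nodes)
  uu <- rep(g$x, each = n_nodes)
  vv <- rep(g$x, times = n_nodes)
  ww <- rep(g$w, each = n_nodes) * rep(g$w, times = n_nodes)
  12 * sum(ww * copula_cdf(uu, vv, spec)) - 3
}

# Kendall's tau: closed forms where available, one-dimensional Debye
# integral for Frank.
.kendall_from_spec <- function(spec) {
  th <- spec$theta
  if (.is_indep(spec)) return(0)
  switch(spec$family,
    clayton = th / (th + 2),
    gumbel  = 1 - 1 / th,
    frank   = {
      d1 <- integrate(function(t) t / expm1(t), 0, th,
                      rel.tol = 1e-12)$value / th
      1 - 4 / th * (1 - d1)
    }
  )
}

#' Convert a copula parameter to a rank correlation
#'
#' @param spec A [copula_spec()].
#' @param measure `"spearman"` or `"kendall"`.
#' @return The corresponding correlation value.
#' @export
theta_to_association <- function(spec, measure = c("spearman", "kendall")) {
  measure <- match.arg(measure)
  stopifnot(inherits(spec, "copula_spec"))
  if (measure == "spearman") .spearman_from_spec(spec) else .kendall_from_spec(spec)
}

#' Solve the copula parameter from a rank correlation
#'
#' Inverts the map `theta -> rho` (Spearman, by two-dimensional
#' Gauss-Legendre quadrature of the copula) or `theta -> tau_K` (Kendall;
#' closed form for Clayton and Gumbel, Debye integral for Frank) with a
#' bracketed root search. Both maps are strictly increasing on the supported
#' positive-dependence range, so the inverse is well defined.
#'
#' @param assoc An [association_spec()], or a plain number interpreted as
#'   Spearman's rho.
#' @param family Copula family name.
#' @return A [copula_spec()] whose implied association reproduces the
#'   requested value to within `1e-6`.
#' @examples
#' association_to_theta(association_spec(0.5, "kendall"), "clayton")  # theta = 2
#' @export
association_to_theta <- function(assoc, family = c("frank", "clayton", "gumbel")) {
  family <- match.arg(family)
  if (is.numeric(assoc)) assoc <- association_spec(assoc, "spearman")
  stopifnot(inherits(assoc, "association_spec"))
  target <- assoc$value
  if (assoc$measure == "kendall") {
    th <- switch(family,
      clayton = 2 * target / (1 - target),
      gumbel  = 1 / (1 - target),
      frank   = NA_real_
    )
    if (!is.na(th)) return(copula_spec(family, th))
  }
  fn <- function(th) {
    spec <- copula_spec(family, th)
    val <- if (assoc$measure == "spearman") .spearman_from_spec(spec) else .kendall_from_spec(spec)
    val - target
  }
  lo <- switch(family, frank = 1e-4, clayton = 1e-4, gumbel = 1 + 1e-7)
  hi <- switch(family, frank = 100, clayton = 50, gumbel = 50)
  if (fn(lo) > 0) return(copula_spec(family, lo))
  if (fn(hi) < 0) {
    stop(sprintf("association %s = %g not attainable for the %s copula within theta <= %g",
                 assoc$measure, target, family, hi), call. = FALSE)
  }
  root <- uniroot(fn, c(lo, hi), tol = 1e-10)
  copula_spec(family, root$root)
}

#' Sample dependent uniform pairs from a copula
#'
#' Draws i.i.d. pairs `(U, V)` from `C` by conditional-distribution
#' inversion: `U ~ Unif(0,1)` and `V` solves `dC/du(U, V) = W` for an
#' independent uniform `W`. Frank and Clayton invert in closed form; Gumbel
#' uses a vectorised bisection on the monotone conditional distribution.
#'
#' @param spec A [copula_spec()].
#' @param n Number of pairs.
#' @param seed Optional integer seed (set via [set.seed()] when non-`NULL`).
#' @return An `n x 2` matrix with columns `u`, `v`; both margins uniform.
#' @export
sample_pairs <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "copula_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  w <- runif(n)
  v <- .conditional_inverse(u, w, spec)
  cbind(u = u, v = v)
}

# Solve dC/du(u, v) = w for v.
.conditional_inverse <- function(u, w, spec) {
  if (.is_indep(spec)) return(w)
  th <- spec$theta
  switch(spec$family,
    frank = {
      y <- w * expm1(-th) / (exp(-th * u) - w * expm1(-th * u))
      -log1p(y) / th
    },
    clayton = {
      (u^(-th) * (w^(-th / (1 + th)) - 1) + 1)^(-1 / th)
    },
    gumbel = {
      lo <- rep_len(1e-14, length(u))
      hi <- rep_len(1 - 1e-14, length(u))
      for (i in seq_len(60)) {
        mid <- (lo + hi) / 2
        below <- copula_partial_u(u, mid, spec) < w
        lo[below] <- mid[below]
        hi[!below] <- mid[!below]
      }
      (lo + hi) / 2
    }
  )
}
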