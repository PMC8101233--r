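specs_for_property_tests <- list(
  copula_spec("frank", 1e-7), copula_spec("frank", 0.5), copula_spec("frank", 2),
  copula_spec("frank", 5), copula_spec("frank", 10),
  copula_spec("clayton", 1e-7), copula_spec("clayton", 0.5), copula_spec("clayton", 2),
  copula_spec("clayton", 5), copula_spec("clayton", 10),
  copula_spec("gumbel", 1 + 1e-7), copula_spec("gumbel", 1.5), copula_spec("gumbel", 2),
  copula_spec("gumbel", 5), copula_spec("gumbel", 10)
)

test_that("copula CDF respects uniform boundaries and Frechet bounds", {
  g <- seq(0.02, 0.98, length.out = 50)
  uu <- rep(g, each = length(g))
  vv <- rep(g, times = length(g))
  for (spec in specs_for_property_tests) {
    expect_equal(copula_cdf(g, rep(1, 50), spec), g, tolerance = 1e-12)
    expect_equal(copula_cdf(rep(1, 50), g, spec), g, tolerance = 1e-12)
    expect_equal(copula_cdf(g, rep(0, 50), spec), rep(0, 50))
    cc <- copula_cdf(uu, vv, spec)
    expect_true(all(cc <= pmin(uu, vv) + 1e-12))
    expect_true(all(cc >= pmax(uu + vv - 1, 0) - 1e-12))
    # exchangeability of all three Archimedean families
    expect_equal(cc, copula_cdf(vv, uu, spec), tolerance = 1e-12)
  }
})

test_that("closed-form values and independence limits are reproduced", {
  expect_equal(copula_cdf(0.5, 0.5, copula_spec("clayton", 2)), 7^(-1/2),
               tolerance = 1e-12)
  expect_equal(copula_cdf(0.3, 1, copula_spec("frank", 5)), 0.3, tolerance = 1e-12)
  near_indep <- copula_spec("frank", 1e-8)
  expect_equal(copula_cdf(0.4, 0.7, near_indep), 0.28, tolerance = 1e-6)
  expect_equal(copula_density(0.37, 0.81, near_indep), 1, tolerance = 1e-6)
  expect_equal(copula_partial_u(0.3, 0.6, near_indep), 0.6, tolerance = 1e-6)
  expect_equal(copula_partial_u(0.3, 1, copula_spec("gumbel", 2)), 1)
})

test_that("density and conditional distribution match finite differences of the CDF", {
  h <- 1e-5
  pts <- list(c(0.5, 0.5), c(0.3, 0.7), c(0.85, 0.2))
  for (spec in list(copula_spec("frank", 4), copula_spec("clayton", 2),
                    copula_spec("gumbel", 1.8))) {
    for (p in pts) {
      u <- p[1]; v <- p[2]
      fd_dens <- (copula_cdf(u + h, v + h, spec) - copula_cdf(u + h, v - h, spec) -
                  copula_cdf(u - h, v + h, spec) + copula_cdf(u - h, v - h, spec)) /
                 (4 * h^2)
      expect_equal(copula_density(u, v, spec), fd_dens, tolerance = 1e-4)
      fd_part <- (copula_cdf(u + h, v, spec) - copula_cdf(u - h, v, spec)) / (2 * h)
      expect_equal(copula_partial_u(u, v, spec), fd_part, tolerance = 1e-5)
    }
  }
})

test_that("density integrates to one and the conditional integrates to v", {
  # the Frank density is bounded, so plain tensor quadrature integrates it
  # over the full square; Clayton/Gumbel have integrable corner
  # singularities and are checked against rectangle probabilities instead
  g <- pracma::gaussLegendre(64, 0, 1)
  uu <- rep(g$x, each = 64); vv <- rep(g$x, 64)
  ww <- rep(g$w, each = 64) * rep(g$w, 64)
  expect_equal(sum(ww * copula_density(uu, vv, copula_spec("frank", 5))), 1,
               tolerance = 1e-4)
  rect <- function(spec, a, b) {
    copula_cdf(b[1], b[2], spec) - copula_cdf(a[1], b[2], spec) -
      copula_cdf(b[1], a[2], spec) + copula_cdf(a[1], a[2], spec)
  }
  for (spec in list(copula_spec("frank", 5), copula_spec("clayton", 2),
                    copula_spec("gumbel", 2))) {
    for (box in list(c(0.05, 0.6), c(0.3, 0.95))) {
      gg <- pracma::gaussLegendre(64, box[1], box[2])
      u2 <- rep(gg$x, each = 64); v2 <- rep(gg$x, 64)
      w2 <- rep(gg$w, each = 64) * rep(gg$w, 64)
      expect_equal(sum(w2 * copula_density(u2, v2, spec)),
                   rect(spec, rep(box[1], 2), rep(box[2], 2)), tolerance = 1e-6)
    }
    # integral over u of dC/du(u, v) recovers C(1, v) = v
    for (v in c(0.25, 0.7)) {
      expect_equal(sum(g$w * copula_partial_u(g$x, rep(v, 64), spec)), v,
                   tolerance = 1e-4)
    }
  }
})

test_that("rank-correlation conversions invert each other", {
  expect_equal(association_to_theta(association_spec(0.5, "kendall"), "clayton")$theta,
               2, tolerance = 1e-9)
  expect_equal(association_to_theta(association_spec(0.5, "kendall"), "gumbel")$theta,
               2, tolerance = 1e-9)
  for (family in c("frank", "clayton", "gumbel")) {
    for (rho in c(0.1, 0.3, 0.5)) {
      spec <- association_to_theta(rho, family)
      expect_equal(theta_to_association(spec, "spearman"), rho, tolerance = 1e-5)
    }
    tau <- 0.35
    spec <- association_to_theta(association_spec(tau, "kendall"), family)
    expect_equal(theta_to_association(spec, "kendall"), tau, tolerance = 1e-6)
  }
  # independence limit: vanishing correlation drives theta to the boundary
  th0 <- association_to_theta(1e-4, "frank")$theta
  expect_lt(th0, 0.01)
})

test_that("invalid parameters are rejected with informative errors", {
  expect_error(copula_spec("frank", -1), "outside the supported range")
  expect_error(copula_spec("gumbel", 0.5), "outside the supported range")
  expect_error(copula_spec("clayton", 1e5), "outside the supported range")
  expect_error(association_spec(-0.2), "positive dependence")
  expect_error(association_spec(1.2), "positive dependence")
})

test_that("conditional-inversion sampling reproduces the analytic copula", {
  n <- 1e5
  for (spec in list(copula_spec("frank", 4), copula_spec("clayton", 2),
                    copula_spec("gumbel", 1.7))) {
    uv <- sample_pairs(spec, n, seed = 101)
    # uniform margins
    ks_u <- max(abs(sort(uv[, 1]) - (seq_len(n) - 0.5) / n))
    ks_v <- max(abs(sort(uv[, 2]) - (seq_len(n) - 0.5) / n))
    expect_lt(ks_u, 1.63 / sqrt(n))  # 1% critical value
    expect_lt(ks_v, 1.63 / sqrt(n))
    # empirical joint CDF agrees with C at grid points within 3 binomial SE
    for (u in c(0.25, 0.5, 0.75)) {
      for (v in c(0.25, 0.5, 0.75)) {
        cc <- copula_cdf(u, v, spec)
        phat <- mean(uv[, 1] <= u & uv[, 2] <= v)
        expect_lt(abs(phat - cc), 3 * sqrt(cc * (1 - cc) / n))
      }
    }
  }
  # Kendall's tau of Clayton(2) draws is 0.5 within Monte-Carlo error
  uv <- sample_pairs(copula_spec("clayton", 2), 2e4, seed = 7)
  tau_hat <- cor(uv[, 1], uv[, 2], method = "kendall")
  expect_lt(abs(tau_hat - 0.5), 3 * sqrt(2 * (2 * 2e4 + 5) / (9 * 2e4 * (2e4 - 1))))
  # independence: empirical Spearman within 3/sqrt(n) of zero
  uv0 <- sample_pairs(copula_spec("frank", 1e-8), 1e5, seed = 11)
  expect_lt(abs(cor(uv0[, 1], uv0[, 2], method = "spearman")), 3 / sqrt(1e5))
  # deterministic under a fixed seed
  expect_identical(sample_pairs(copula_spec("frank", 4), 50, seed = 3),
                   sample_pairs(copula_spec("frank", 4), 50, seed = 3))
})
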