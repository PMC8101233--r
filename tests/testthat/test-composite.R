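test_that("composite survival matches the minimum of independent exponentials", {
  lam <- c(0.7, 0.3)
  m <- calibrate_model(component_spec(1, p_cs_exponential(1, lam[1], lam[2], 1)),
                       component_spec(1, p_cs_exponential(2, lam[1], lam[2], 1)),
                       indep_copula(), tau = 1)
  t <- c(0.1, 0.4, 0.9)
  expect_equal(composite_survival(m, t, 0), exp(-sum(lam) * t), tolerance = 1e-6)
  expect_equal(composite_survival(m, 0, 0), 1)
  # constant cause-specific hazards equal the component rates
  expect_equal(cause_specific_hazard(m, t, 1, 0), rep(lam[1], 3), tolerance = 1e-6)
  expect_equal(cause_specific_hazard(m, t, 2, 0), rep(lam[2], 3), tolerance = 1e-6)
})

test_that("composite survival under dependence matches Monte-Carlo sampling", {
  m <- calibrate_model(component_spec(1.4, 0.35, 0.8),
                       component_spec(0.8, 0.25, 0.7),
                       frank_for_rho(0.5), tau = 1)
  n <- 2e5
  uv <- sample_pairs(m$copula, n, seed = 202)
  t1 <- m$scales0[1] * (-log1p(-uv[, 1]))^(1 / m$shapes[1])
  t2 <- m$scales0[2] * (-log1p(-uv[, 2]))^(1 / m$shapes[2])
  tstar <- pmin(t1, t2)
  for (t in c(0.25, 0.5, 0.75, 1)) {
    s_true <- composite_survival(m, t, 0)
    expect_lt(abs(mean(tstar > t) - s_true), 3 * sqrt(s_true * (1 - s_true) / n))
  }
})

test_that("cause-specific hazards sum to the derivative of the log survival", {
  for (model in list(grid_model(0.3, 0.1, rho = 0.5),
                     grid_model(0.2, 0.2, shape1 = 0.5, shape2 = 2, rho = 0.3),
                     zodiac_model(5))) {
    for (group in 0:1) {
      t <- model$tau * c(0.2, 0.5, 0.8)
      h <- model$tau * 1e-6
      total <- cause_specific_hazard(model, t, 1, group) +
               cause_specific_hazard(model, t, 2, group)
      fd <- -(log(composite_survival(model, t + h, group)) -
              log(composite_survival(model, t - h, group))) / (2 * h)
      expect_equal(total, fd, tolerance = 1e-5)
    }
  }
})

test_that("density, survival and hazard of the composite endpoint are consistent", {
  m <- grid_model(0.3, 0.2, shape1 = 2, shape2 = 0.5, rho = 0.5)
  cv <- hr_star_curve(m, n_grid = 200)
  expect_equal(cv$density0, cv$hazard0 * cv$survival0, tolerance = 1e-8)
  expect_equal(cv$density1, cv$hazard1 * cv$survival1, tolerance = 1e-8)
  expect_equal(cv$hazard0, cv$cause1_0 + cv$cause2_0, tolerance = 1e-8)
  expect_true(all(diff(cv$survival0) < 0))
  # integrating the composite density recovers the event probability
  for (group in 0:1) {
    g <- pracma::gaussLegendre(200, 0, 1)
    t <- m$tau * g$x^2
    w <- g$w * 2 * m$tau * g$x
    expect_equal(sum(w * composite_density(m, t, group)),
                 1 - composite_survival(m, m$tau, group), tolerance = 1e-6)
  }
})

test_that("HR*(t) is flat in null and proportional cases, curved otherwise", {
  null_model <- grid_model(hr1 = 1, hr2 = 1)
  expect_equal(hr_star_curve(null_model, 100)$hr_star, rep(1, 100), tolerance = 1e-10)
  # cause_specific_ph with equal HRs: exactly proportional all-cause hazards
  ph <- grid_model(hr1 = 0.7, hr2 = 0.7, rho = 0.5, construction = "cause_specific_ph")
  expect_equal(hr_star_curve(ph, 100)$hr_star, rep(0.7, 100), tolerance = 1e-8)
  expect_equal(gahr(ph), 0.7, tolerance = 1e-8)
  # distinct component effects make the composite hazard ratio time-varying
  mixed <- grid_model(hr1 = 0.9, hr2 = 0.6, rho = 0.5)
  expect_gt(diff(range(hr_star_curve(mixed, 500)$hr_star)), 0.01)
})

test_that("cause_specific_ph scales each cause hazard by its hazard ratio exactly", {
  m <- grid_model(0.3, 0.2, hr1 = 0.8, hr2 = 0.6, rho = 0.5,
                  construction = "cause_specific_ph")
  t <- c(0.1, 0.5, 0.9)
  for (k in 1:2) {
    expect_equal(cause_specific_hazard(m, t, k, 1),
                 m$hr[k] * cause_specific_hazard(m, t, k, 0), tolerance = 1e-12)
  }
})

test_that("gAHR is invariant to rescaling the follow-up time", {
  a <- calibrate_model(component_spec(1, 0.3, 0.8), component_spec(2, 0.2, 0.6),
                       frank_for_rho(0.3), tau = 1)
  b <- calibrate_model(component_spec(1, 0.3, 0.8), component_spec(2, 0.2, 0.6),
                       frank_for_rho(0.3), tau = 24)
  expect_equal(gahr(a), gahr(b), tolerance = 1e-6)
})

test_that("quadrature and equidistant-grid evaluations of gAHR agree", {
  for (model in list(grid_model(0.3, 0.1, rho = 0.5),
                     grid_model(0.2, 0.2, shape1 = 0.5, shape2 = 2, rho = 0.3),
                     zodiac_model(4))) {
    expect_equal(gahr(model, method = "quadrature"),
                 gahr(model, method = "grid", n_grid = 1000), tolerance = 2e-3)
  }
})

test_that("the naive summary is the arithmetic mean of the component effects", {
  expect_equal(naive_hr(0.6, 0.8), 0.7)
  expect_equal(naive_hr(0.91, 0.77), 0.84)
  expect_equal(naive_hr(0.85, 0.85), 0.85)
  eff <- effect_summary(grid_model())
  expect_equal(eff$p_star_avg, (eff$p_star0 + eff$p_star1) / 2, tolerance = 1e-12)
  expect_true(eff$gahr > 0 && eff$gahr < 1)
})
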