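test_that("logrank statistic reproduces hand-computed and limiting cases", {
  # one event in group 1, one subject at risk in each group
  expect_equal(logrank_statistic(time = c(2, 1), status = c(0, 1), group = c(0, 1)),
               (1 - 0.5) / sqrt(0.25))
  # swapping group labels flips the sign exactly
  set.seed(5)
  d <- simulate_trial(grid_model(), n = 200, seed = 5)
  z <- logrank_statistic(d$time, d$status, d$group)
  expect_equal(logrank_statistic(d$time, d$status, 1 - d$group), -z, tolerance = 1e-12)
  expect_error(logrank_statistic(c(1, 2), c(0, 0), c(0, 1)), "no composite events")
  expect_error(logrank_statistic(c(1, 2), c(1, 1), c(0, 0)), "both groups")
})

test_that("logrank statistic agrees with the survival-package implementation", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (r in seq_len(1000)) {
    n <- sample(20:60, 1)
    time <- rexp(n)
    if (r %% 3 == 0) time <- round(time, 1)  # force ties regularly
    time <- pmax(time, 1e-3)
    status <- rbinom(n, 1, 0.8)
    group <- rbinom(n, 1, 0.5)
    if (sum(status) == 0 || length(unique(group)) < 2) next
    z <- logrank_statistic(time, status, group)
    chi <- survival::survdiff(survival::Surv(time, status) ~ group)$chisq
    expect_equal(z^2, chi, tolerance = 1e-8)
  }
})

test_that("simulated trials reproduce the analytic event structure", {
  m <- grid_model(0.3, 0.2, hr1 = 0.8, hr2 = 0.6, rho = 0.5)
  n <- 4e4
  d <- simulate_trial(m, n, seed = 99)
  expect_identical(nrow(d), as.integer(n))
  expect_identical(sum(d$group == 1), as.integer(n / 2))
  expect_true(all(d$time[d$status == 0] == m$tau))
  expect_true(all(is.na(d$cause[d$status == 0])))
  for (g in 0:1) {
    dg <- d[d$group == g, ]
    p_star <- 1 - composite_survival(m, m$tau, g)
    expect_lt(abs(mean(dg$status) - p_star),
              3 * sqrt(p_star * (1 - p_star) / nrow(dg)))
    # cause-1 share among events matches the cause-specific split
    p1 <- observed_probability(m, 1, g, mode = "cause_specific")
    share <- p1 / p_star
    obs_share <- mean(dg$cause[dg$status == 1] == 1)
    expect_lt(abs(obs_share - share), 3 * sqrt(share * (1 - share) / sum(dg$status)))
  }
  # empirical rank correlation of the latent pairs matches the request
  uv <- sample_pairs(m$copula, 5e4, seed = 1)
  expect_lt(abs(cor(uv[, 1], uv[, 2], method = "spearman") - 0.5), 3 / sqrt(5e4))
  # bit-reproducible under a fixed seed
  expect_identical(simulate_trial(m, 500, seed = 31), simulate_trial(m, 500, seed = 31))
})

test_that("cause_specific_ph simulation matches its analytic survival", {
  m <- grid_model(0.3, 0.2, hr1 = 0.9, hr2 = 0.6, rho = 0.5,
                  construction = "cause_specific_ph")
  d <- simulate_trial(m, 4e4, seed = 17)
  d1 <- d[d$group == 1, ]
  for (t in c(0.3, 0.7, 1)) {
    s_true <- composite_survival(m, t, 1)
    expect_lt(abs(mean(d1$time > t | (d1$time == t & d1$status == 0)) - s_true),
              3.5 * sqrt(s_true * (1 - s_true) / nrow(d1)))
  }
})

test_that("empirical power is reproducible and controls the type-I error", {
  m0 <- grid_model(hr1 = 1, hr2 = 1)
  s1 <- empirical_power(m0, n = 400, reps = 2000, alpha = 0.025, seed = 77)
  s2 <- empirical_power(m0, n = 400, reps = 2000, alpha = 0.025, seed = 77)
  expect_identical(s1$power_hat, s2$power_hat)
  expect_lt(abs(s1$power_hat - 0.025), 3 * sqrt(0.025 * 0.975 / 2000))
  # a sized scenario reaches its target power
  des <- design_scenario(component_spec(1, 0.3, 0.8), component_spec(1, 0.3, 0.6),
                         assoc = 0.3)
  sim <- empirical_power(des$model, des$n, reps = 2000, alpha = 0.025, seed = 123)
  expect_lt(abs(sim$power_hat - 0.80), 3 * sim$se + 0.01)
})

test_that("grid machinery enumerates and summarises scenarios correctly", {
  g1 <- scenario_grid(1)
  g2 <- scenario_grid(2)
  expect_identical(nrow(g1), 405L)
  expect_identical(nrow(g2), 3240L)
  expect_false(any(g1$p1 == 0.5 & g1$p2 == 0.5))
  expect_false(any(g2$shape1 == 1 & g2$shape2 == 1))
  # one-row grid agrees with the scenario pipeline
  row <- data.frame(p1 = 0.3, p2 = 0.1, hr1 = 0.8, hr2 = 0.6, rho = 0.3,
                    shape1 = 1, shape2 = 1)
  res <- run_grid(row)
  ref <- design_scenario(component_spec(1, 0.3, 0.8), component_spec(1, 0.1, 0.6),
                         assoc = 0.3)
  expect_equal(res$gahr, ref$gahr, tolerance = 1e-9)
  expect_identical(as.integer(res$events), ref$events)
  expect_identical(as.integer(res$n), ref$n)
  expect_false(res$excluded)
  # degenerate copula table: every decile equals the single scenario's gAHR
  tab <- gahr_copula_table(families = "frank", grid = row)
  expect_equal(unname(unlist(tab[1, -1])), rep(ref$gahr, 9), tolerance = 1e-9)
})

test_that("grid power summaries stratify without losing scenarios", {
  rows <- scenario_grid(1)[c(1, 50, 200, 350), ]
  res <- run_grid(rows, reps = 300, seed = 9)
  expect_true(all(!is.na(res$power_hat[!res$excluded])))
  summ <- summarise_grid(res)
  expect_identical(summ$scenarios[summ$stratum == "global"], sum(!res$excluded))
  expect_true(all(c("min", "median", "max") %in% names(summ)))
})
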