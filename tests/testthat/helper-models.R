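# Shared builders for small calibrated models used across test files.

# Independence is represented by a vanishing Frank parameter.
indep_copula <- function() copula_spec("frank", 1e-9)

frank_for_rho <- function(rho) association_to_theta(rho, "frank")

# Exponential margins, both components cause-specific: the workhorse grid
# scenario shape.
grid_model <- function(p1 = 0.3, p2 = 0.1, hr1 = 0.8, hr2 = 0.6, rho = 0.3,
                       shape1 = 1, shape2 = 1, tau = 1,
                       construction = "marginal_ph", family = "frank") {
  calibrate_model(component_spec(shape1, p1, hr1),
                  component_spec(shape2, p2, hr2),
                  association_to_theta(rho, family), tau,
                  construction = construction)
}

# Lung-cancer case-study scenario k (1..5): death marginal, progression
# cause-specific, tau = 24 months.
zodiac_model <- function(k, construction = "marginal_ph") {
  s <- zodiac_scenarios()[k, ]
  calibrate_model(component_spec(s$shape1, s$p1, s$hr1, s$obs1),
                  component_spec(s$shape2, s$p2, s$hr2, s$obs2),
                  frank_for_rho(s$rho), s$tau, construction = construction)
}

# Closed-form cause-specific probability for independent exponential
# margins: P(T_k < tau, T_k < T_other) = lam_k/(lam1+lam2) (1 - e^-(lam1+lam2)tau).
p_cs_exponential <- function(k, lam1, lam2, tau) {
  lam <- c(lam1, lam2)
  lam[k] / sum(lam) * (1 - exp(-sum(lam) * tau))
}
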