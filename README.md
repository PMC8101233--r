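# gahrdesign

Sample-size and power calculation for two-arm randomized trials whose
primary endpoint is a **two-component composite time-to-event outcome** —
progression-free survival, MACE-style composites, infection-plus-death
endpoints, and the like.

## The problem

When a trial's primary endpoint is the time to the *first* of two events,
the hazard ratio of the composite, HR\*(t), is generally **not constant
over time even when each component has perfectly proportional hazards**.
Plugging a single "composite HR" guess into Schoenfeld's formula then
produces a sample size whose operating characteristics are unknown. This
package implements a design pipeline built instead on the **truncated
geometric average hazard ratio**,

```
gAHR(τ) = exp{ ∫₀^τ log HR*(t) f*⁽ᵃ⁾(t) dt / p*⁽ᵃ⁾(τ) },
```

where `f*⁽ᵃ⁾ = (f*⁽⁰⁾ + f*⁽¹⁾)/2` is the average density of the composite
event time and `p*⁽ᵃ⁾(τ)` the average probability of observing the
composite event by the end of follow-up τ. The gAHR is the natural effect
summary for the logrank test: the noncentrality parameter of the one-sided
logrank statistic Z\* is

```
μ*(τ) = √(n π(1−π) p*⁽ᵃ⁾(τ)) · log gAHR(τ),
```

so the required number of composite events and the total sample size are

```
e* = (z_α + z_β)² / (π(1−π) · log² gAHR(τ)),     n = e* / p*⁽ᵃ⁾(τ)
```

— Schoenfeld's formula with gAHR(τ) in the hazard-ratio slot, valid
without any proportionality assumption on the composite.

To obtain gAHR(τ) and p\*⁽ᵃ⁾(τ) from quantities a trialist can actually
anticipate, the joint law of the two latent component times is modelled
with an **Archimedean copula** (Frank, Clayton or Gumbel; association
given as Spearman's ρ or Kendall's τ) and **Weibull margins**. The scale
parameters are calibrated so the model reproduces the anticipated
control-group observation probabilities — either marginal,
`P(T_k < τ)`, or cause-specific, `P(T_k < τ, T_k < T_other)`, per
component — and the treatment group is built from the anticipated
component hazard ratios. All analytic quantities (HR\*(t) curves,
cause-specific hazards, gAHR, p\*) and a Monte-Carlo engine (competing
risks data generation, logrank test, empirical power, full scenario grids)
derive from that calibrated model.

## Worked example

A lung-cancer trial with progression-free survival as primary endpoint:
death observed marginally (`p = 0.59` by 24 months, HR 0.91), progression
observed cause-specifically (`p = 0.74`, HR 0.77), moderate correlation
(ρ = 0.5), 90% power at two-sided level 0.0242:

```r
library(gahrdesign)

res <- design_scenario(
  component_spec(shape = 1, p0 = 0.59, hr = 0.91, observation = "marginal"),
  component_spec(shape = 1, p0 = 0.74, hr = 0.77, observation = "cause_specific"),
  assoc = 0.5, family = "frank", tau = 24,
  params = design_params(alpha = 0.0242, power = 0.90, two_sided = TRUE))
res
#> Composite-endpoint design (gahr method)
#>   gAHR(tau)    = 0.7992   (naive HR = 0.8400)
#>   p*_avg(tau)  = 0.8971
#>   events e*    = 996
#>   sample size  = 1110 (both groups)
#>   mu*(tau)     = -3.536

empirical_power(res$model, res$n, reps = 2000, alpha = 0.0121, seed = 1)
#> Empirical power: 0.9060 (MC SE 0.0065) from 2000 trials of n = 1110

range(hr_star_curve(res$model)$hr_star)
#> [1] 0.779 0.817
```

Reading the output: although the component hazard ratios are 0.91 and
0.77, the composite hazard ratio drifts between 0.78 and 0.82 over
follow-up; its geometric average 0.799 — not the naive mean 0.84 — is
what determines the 996 required events. Because 89.7% of patients are
expected to experience the composite event, 1,110 patients suffice, and
simulation confirms the design attains its 90% target power.

Scenario files (YAML) and a command-line front end are provided:

```sh
Rscript inst/scripts/composite-design.R design --config inst/extdata/arrest.yaml --out out/
Rscript inst/scripts/composite-design.R grid --setting 1 --out out/
Rscript inst/scripts/composite-design.R tables --out out/
```

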