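# Lung-cancer PFS case study, scenario 1: exponential margins, weak
# correlation between death and progression.
component1:
  shape: 1.0
  p0: 0.59
  hr: 0.91
  observation: marginal
component2:
  shape: 1.0
  p0: 0.74
  hr: 0.77
  observation: cause_specific
association:
  measure: spearman
  value: 0.1
copula: frank
tau: 24
alpha: 0.0242
two_sided: true
power: 0.90
allocation: 0.5
construction: marginal_ph
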