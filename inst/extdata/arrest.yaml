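# S. aureus bacteraemia case study: death (marginal) plus bacteriological
# failure/recurrence (cause-specific), 12-week follow-up.
component1:
  shape: 0.7
  p0: 0.14
  hr: 0.95
  observation: marginal
component2:
  shape: 0.91
  p0: 0.05
  hr: 0.35
  observation: cause_specific
association:
  measure: spearman
  value: 0.1
copula: frank
tau: 12
alpha: 0.025
power: 0.80
allocation: 0.5
construction: marginal_ph
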