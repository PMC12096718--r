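# Default piperacillin population PK model (two-compartment, no covariates,
# developed-from-critically-ill structure). Package defaults calibrated to
# first-dose extended-infusion exposure (median Cmax ~230 mg/L after a
# 4 g / 0.5 h load; trough ~29 mg/L on 4+4 g q6h; terminal half-life
# ~1.6-2.2 h). Between-subject variability is wider than for meropenem since
# no covariate explains renal elimination.
drug: piperacillin
typical:
  CL: 13.0   # L/h
  V1: 12.0   # L
  Q: 12.0    # L/h
  V2: 12.0   # L
covariate_effects: []
omega:
  CL: 0.45
  V1: 0.35
  Q: 0.30
  V2: 0.30
error:
  additive: 0.5        # mg/L
  proportional: 0.12
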