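# Default meropenem population PK model (two-compartment; CrCL and age as
# power covariates on CL, body weight on V1). Typical values and variability
# are package defaults calibrated to first-dose extended-infusion exposure in
# general ICU cohorts (median Cmax ~57 mg/L after a 1 g / 0.5 h load into a
# ~80 kg adult; terminal half-life ~1.4 h at eGFR > 90, ~2.5-3 h below).
drug: meropenem
typical:
  CL: 12.0     # L/h at crcl 100 mL/min, age 55 y
  V1: 12.0     # L at 70 kg
  Q: 8.0       # L/h
  V2: 8.0      # L
covariate_effects:
  - parameter: CL
    covariate: crcl
    form: power
    coefficient: 0.62
    reference: 100
  - parameter: CL
    covariate: age
    form: power
    coefficient: -0.25
    reference: 55
  - parameter: V1
    covariate: weight
    form: power
    coefficient: 1.0
    reference: 70
omega:        # log-normal between-subject SDs
  CL: 0.35
  V1: 0.30
  Q: 0.25
  V2: 0.25
error:
  additive: 0.2        # mg/L
  proportional: 0.12   # unitless
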