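# Default run configuration for polymyxin B feedback-control simulation.
# Units are embedded in key names (L/h/kg, mg/kg, h, mg.h/L).
# Provenance: cl_L_h_kg 0.0276 and bsv_cv cl 0.324 are the published
# population values; the window (50, 75, 100) and the regimen
# (2.5 mg/kg over 2 h load; 1.5 mg/kg over 1 h q12h) are published.
# v1/q/v2 typical values and their bsv, the residual-error magnitudes
# and default_weight_kg are package defaults (not published): volumes
# chosen for Vss ~0.5 L/kg and terminal half-life ~12-14 h; residual
# error is a typical assay+model magnitude for population PK.
population:
  cl_L_h_kg: 0.0276
  v1_L_kg: 0.25
  q_L_h_kg: 0.06
  v2_L_kg: 0.25
  bsv_cv:
    cl: 0.324
    v1: 0.3
    q: 0.3
    v2: 0.3
  residual:
    proportional_cv: 0.2
    additive_sd_mg_L: 0.05
regimen:
  loading_mg_kg: 2.5
  loading_duration_h: 2.0
  maintenance_mg_kg: 1.5
  maintenance_duration_h: 1.0
  interval_h: 12.0
window:
  lower_mg_h_L: 50.0
  mid_mg_h_L: 75.0
  upper_mg_h_L: 100.0
simulation:
  n_subjects: 5000.0
  seed: 42.0
  default_weight_kg: 70.0
strategies:
- label: none
  times_h: []
- label: '12'
  times_h: 12.0
- label: '24'
  times_h: 24.0
- label: '2,12'
  times_h:
  - 2.0
  - 12.0
- label: '2,24'
  times_h:
  - 2.0
  - 24.0
- label: '4,24'
  times_h:
  - 4.0
  - 24.0
- label: '12,24'
  times_h:
  - 12.0
  - 24.0
- label: '2,4,12'
  times_h:
  - 2.0
  - 4.0
  - 12.0
- label: '2,12,24'
  times_h:
  - 2.0
  - 12.0
  - 24.0
- label: '4,12,24'
  times_h:
  - 4.0
  - 12.0
  - 24.0
- label: '2,4,12,24'
  times_h:
  - 2.0
  - 4.0
  - 12.0
  - 24.0
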