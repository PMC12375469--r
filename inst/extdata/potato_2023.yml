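# Calibrated potato parameter set (canopy rates per growing degree day).
kind: crop
params:
  cc0: 0.6
  ccx: 92.0
  cgc: 0.018
  cdc: 0.008
  t_base: 2.0
  t_upper: 26.0
  zr_min: 0.15
  zr_max: 0.47
  kctr: 1.10
  hi0: 0.75
  wp: 19.0
  extraction: [0.40, 0.30, 0.20, 0.10]
  p_exp_upper: 0.26
  p_exp_lower: 0.66
  shape_exp: 3.0
  p_sto_upper: 0.65
  shape_sto: 3.0
  p_sen_upper: 0.69
  shape_sen: 3.0
  ks_cold: 1.0
  f_hi: 1.0
  ke_max: 1.10
  dry_matter_fraction: 0.20
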