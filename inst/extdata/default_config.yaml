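# Default run configuration: a single Cyanobium-like alpha-carboxysome at
# 20 mM external bicarbonate, pH 8.0, air-equilibrated O2, with the
# RuBP-regulated carboxysomal CA (half-maximal activation 18 uM, Hill
# slope 2.214, CA factor 100,000) and the Cyanobium Rubisco kinetics.
# Units are spelled out in every key name.
seed: 1
output_dir: "."
model:
  k1_per_s: 0.05
  k2_per_mM_s: 100.0
  ca_factor_carboxysome: 100000.0
  k_half_uM: 18.0
  hill_slope: 2.214
  kcat_c_per_s: 9.4
  km_co2_uM: 169.0
  km_o2_mM: 1.4
  kcat_o_per_s: 1.42
  km_rubp_uM: 40.0
  e_sites_mM: 5.68
  external_hco3_mM: 20.0
  external_ph: 8.0
  external_o2_mM: 0.25
  external_co2_mM: 0.01
  diameter_nm: 100.0
  unstirred_volume_ratio: 10.0
  n_h_carboxylation: 2.0
  pka_rubp: 6.7
  speciation: pka
  clamp_rubp: false
  transport_ext_per_s:
    co2: 1000.0
    hco3: 1000.0
    h: 1000.0
    o2: 1000.0
    rubp: 1000.0
  transport_shell_per_s:
    co2: 100.0
    hco3: 100.0
    h: 1000.0
    o2: 100.0
    rubp: 10.0
sweep:
  rubp_min_mM: 0.0001
  rubp_max_mM: 5.0
  n_levels: 20
solver:
  tol_mM_s: 1.0e-10
mims:
  gap_min: 0.5
  log_base: ln
generator:
  trace_noise_sd: 0.01
  response_noise_sd: 0.02
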