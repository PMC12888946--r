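seed: 1
outdir: litt_out
phantom:
  tumor_radius_mm: 10.0
  spacing_mm: 0.5
  shells_mm:
    brain: 15.0
    csf_general: 3.0
    skull: 7.0
  stage_z_mm:
  - -5.0
  - 0.0
  - 5.0
materials: []
blood:
  density: 1050.0
  heat_capacity: 3617.0
  temperature_C: 37.0
optics:
  mu_native_per_mm:
    brain: 0.35
    tumor: 0.35
    skull: 0.0
    csf_general: 0.0
    csf_ventricle: 0.0
  coagulation_factor: 1.5
  mode: cop
  recompute_tol: 0.01
damage:
  A_per_s: 3.1e+98
  Ea_J_per_mol: 628000.0
  peritumoral_margin_mm: 5.0
controller:
  kp: 7.5
  ki: 0.5
  kd: 0.0
  t_setpoint_C: 60.0
  t_cap_C: 100.0
  omega_setpoint: 0.99
  p_max_W: 15.0
  output_mode: watts
  hysteresis_C: 2.0
  feedback_delay_steps: 0
solver:
  dt_s: 1.0
  scheme: bdf2
  prop_cap_C: 90.0
bc:
  h_outer: 5.0
  t_outer_C: 20.0
  h_catheter: 100.0
  t_catheter_C: 20.0
laser:
  source_model: pslh
  n_sub: 10
treat:
  t_max_s: 7200.0
uq:
  n_train: 20
  n_verify: 10
  n_base: 32768
  spread: 0.2
  n_propagate: 2000
  spacing_mm: 1.0
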