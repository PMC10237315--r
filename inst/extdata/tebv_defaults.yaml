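# Default experiment configuration: perfused TEBV-on-a-chip study conditions.
# Units are stated in each key name; every value here equals the built-in
# default of pipeline_config().
geometry:
  a_mm: 1.0        # inner radius (2.0 mm inner diameter)
  b_mm: 2.5        # outer radius (5.0 mm outer diameter)
  length_mm: 20    # perfused segment length
  p_ext_Pa: 0      # external reference pressure; d = 2a at zero transmural p
wall:
  E_kPa: 28.6      # Hookean Young's modulus of the vessel wall
  nu: 0.45         # Poisson ratio (nearly incompressible hydrogel)
  regime: plane_strain
fluid:
  K_cP: 11.885     # power-law consistency (cP at 1 1/s)
  "n": -0.2188       # viscosity exponent (shear thinning)
  density_kg_m3: 1000
  clamp: [1, 1000] # calibrated shear-rate window, 1/s
inlet:
  U_mean_mm_s: 2.65   # 500 uL/min through the 2.0 mm lumen
  period_s: 1         # 1 Hz pulse
  shape: offset_sinusoid
  PI: 1               # pulsatility index (Umax - Umin) / Umean
  phase_rad: 0
outlet:
  p_min_Pa: 640
  p_max_Pa: 780
  period_s: 1
  phase_rad: 0        # in phase with the inlet
solver:
  n_nodes: 33
  dt_s: 0.01
  max_cycles: 40
  periodicity_tol: 1.0e-5
  theta: 0.6
materials:
  model_form: stretch_linear
  fit_intercept: true
comparison:
  Q_nominal_uL_min: 500
  d0_exp_mm: 2.0
  eps_frac: 0.05
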