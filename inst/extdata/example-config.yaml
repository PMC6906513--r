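# Example turbmri pipeline configuration (see ?readRunConfig).
output: turbmri-out
seed: 1
density: 1200          # fluid density used by estimation/metrics, kg/m^3
phantom:
  dims: [24, 24, 48]
  spacing: 0.625       # mm
  stenosis: 0.64       # area-reduction fraction
  peak_velocity: 2.0   # m/s
  peak_ivsd: 0.8       # m/s (patient-like); 0.3 for healthy-like
  density: 1200
scheme:
  vencs: [0.5, 1.5, 4.5]
  include_reference: true
experiment:
  snr_list: [40, 30, 20]
  factor_list: [1, 2, 4]
  n_reps: 5
  median_size: 3
  method: bayes
recon:
  block_size: 22
  lambda: 0.005
  max_iter: 50
  tol: 1.0e-6
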