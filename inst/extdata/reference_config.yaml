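# Reference pipeline configuration: the measured/estimated kinetic constants
# and abundances of the yeast pheromone response system.
variant: simplified
params:
  Kd_LR: 5.6
  koff_LR: 0.001
  Kd_RG: 33.0
  koff_RG: 0.1
  Kd_GdGbg: 0.01
  kA_Gd: 3.2
  kE_G: 0.00062
  kE_RG: 0.00062
  kE_LRG: 1.5
  kH_Gt: 0.002
  kH_RGt: 0.11
  kH_LRGt: 0.11
abundances:
  R_tot: 1400.0
  G_tot: 860.0
  V_cyt: 36.4
l_grid:
  lo: 1.0e-3
  hi: 1.0e+5
  points: 25
solver:
  tol: 1.0e-9
  maxit: 400
  method: hybrid
sampler:
  n_points: 1000
  span: 8
  sampled: [Kd_LR, koff_LR, Kd_RG, koff_RG, Kd_GdGbg, kA_Gd,
            kE_G, kE_RG, kE_LRG, kH_Gt, kH_RGt, kH_LRGt]
robustness:
  multipliers: [0.1, 1.0, 10.0]
  amplitude_tol: 1.5
  ec50_tol: 3.0
  amplitude_floor: 0.05
  dora_band: [0.3333333333333333, 3.0]
  grid_points: 20
  grid_decades: 4
seed: 1
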