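model: circuit_global
parameters:
  beta_m1: 0.667
  gamma_m1: 0.00067
  beta_y1s: 1.39e-05
  gamma_y1s: 4.63e-05
  gamma_y1: 4.63e-05
  gamma_y1r: 4.63e-05
  theta_x: 0.002
  theta_y1: 1.5
  n1: 1.5
  y1_0: 85.0
  beta_m2s: 0.0
  beta_m2: 0.083
  gamma_m2: 0.00083
  beta_y2: 0.0014
  gamma_y2: 4.63e-05
  alpha_x: 0.35
  x_e: 45.0
  n_x: 2.0
global_variable:
  beta_g: 0.000126
  gamma_g: 3.0e-06
  coupled:
  - tl_y1s
  - tl_y1r
  - tl_y2
adh1_estradiol: yes
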