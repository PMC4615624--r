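model: simple_cascade_global
parameters:
  beta_y1s: 0.01
  gamma_y1s: 6.7e-06
  gamma_y1: 6.7e-06
  theta_x: 0.001
  theta_y1: 1.5
  n1: 3.0
  y1_0: 85.0
  beta_m2s: 0.0083
  beta_m2: 0.1583
  gamma_m2: 0.00083
  beta_y2: 0.0014
  gamma_y2: 0.00014
global_variable:
  beta_g: 1.5e-06
  gamma_g: 3.0e-08
  coupled:
  - syn_y1s
  - tl_y2
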