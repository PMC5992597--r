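version: '1'
parameters:
  beta_mS: 3.0
  beta_mC1: 1.0
  beta_T: 1.0
  beta_rC: 1.0
  beta_rAB: 1.0
  a0: 0.05
  a_C: 1.0
  a_S: 0.5
  K_SC1: 0.5
  K_SS: 0.5
  K_ST: 0.2
  K_C1S: 0.2
  K_rCS: 2.0
  K_TS: 0.5
  K_TP: 0.5
  K_rABT: 0.5
  hill_n: 2.0
  tau_S: 1.0
  tau_C1: 1.0
  delta_mS: 1.0
  delta_S: 1.0
  delta_mC1: 1.0
  delta_C1: 1.0
  delta_T: 1.0
  delta_rC: 0.5
  delta_rAB: 0.5
  kappa: 200.0
  D: 1.5
  autoregulation: yes
  diffusion: yes
geometry:
  n_cells: 10
  prif:
  - 1.0
  - 1.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
  - 0.0
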