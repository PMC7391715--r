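device:
  W: 1.0e-07
  L: 1.0e-07
  C_G: 0.0002
  tg_delta: 0.0038
  g_m: 1.0e-06
  N_ot: 1.0e+12
  T: 300.0
trap:
  tau_c0: 0.002049180328
  tau_e0: 0.002049180328
  alpha: 0.5
  v0: 0.0
  q_star: 8.01088317e-20
simulation:
  duration: 40.0
  dt: 0.0001
  seed: 1.0
  v_g: 0.0
analysis:
  theta: 20.0
  f1: 1.0
  f2: 100.0
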