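# Generic size-structured model parameterized for small invertebrates:
# individuals carry a single body mass (no reversible reserves) and shrink at
# metamorphosis instead of burning fat. Units as in fat_reserves.
params:
  delta: 0.1
  X1_max: 0.165
  X2_max: 0.165
  w_min: 0.0005
  w_A: 0.01
  kappa_e: 0.6
  conv: 0.001
  rho: 0.5
  meta_loss: 0.3
  A1_max: 5.0
  w_opt1: 0.0005
  alpha1: 0.5
  A2_max: 20.0
  w_opt2: 0.01
  alpha2: 0.5
  spec_exp: 1.0
  xi1: 0.02
  xi2: 0.75
  m1: 0.01
  m2: 1.0
  kappa_x: 0.7
  kappa_rep: 0.9
  c0: 0.00015
  c1: 2.0
  q_b: 0.0
  q_starv: 0.02
  mu_L: 0.03
  mu_J: 0.005
  mu_A: 0.005
  mu_L_extra: 0.0
  reserves: 0
  h: 0.25
  max_age: 3000.0   # integration horizon (days)
  s_eps: 1.0e-7     # survival truncation
traits0:
  psi_L: 0.0
  theta: 0.8
  w_J: 0.002
  w_b: 0.00015
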