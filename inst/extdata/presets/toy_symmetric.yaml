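# Deliberately simple symmetric configuration used as a closed-form oracle
# for the adaptive-dynamics solvers: two identical resources available from
# birth (w_min = 0 effectively), direct development (w_b >= w_J) with theta
# fixed at 0, so the single evolving trait psi_L sets lifelong specialization.
# By the exchange symmetry of the two resources the selection gradient on
# psi_L vanishes at exactly psi_L = 1/2.
params:
  delta: 0.1
  X1_max: 0.1
  X2_max: 0.1
  w_min: 0.0002
  w_A: 0.02
  kappa_e: 0.6
  conv: 0.001
  rho: 0.0
  meta_loss: 0.0
  A1_max: 30.0
  w_opt1: 0.005
  alpha1: 0.6
  A2_max: 30.0
  w_opt2: 0.005
  alpha2: 0.6
  spec_exp: 1.0
  xi1: 0.009
  xi2: 0.75
  m1: 0.01
  m2: 1.0
  kappa_x: 0.7
  kappa_rep: 0.9
  c0: 0.00005
  c1: 2.0
  q_b: 0.2
  q_starv: 0.02
  mu_L: 0.01
  mu_J: 0.005
  mu_A: 0.005
  mu_L_extra: 0.0
  reserves: 1
  h: 0.25
  max_age: 3000.0   # integration horizon (days)
  s_eps: 1.0e-7     # survival truncation
traits0:
  psi_L: 0.3
  theta: 0.0
  w_J: 0.00011
  w_b: 0.0005
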