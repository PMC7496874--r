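# Fat-reserves model: consumers with irreversible (structural) and reversible
# (fat/gonad) body mass feeding on two semichemostat resources.
# Units: mass g, resource density mg/L, time days, clearance L/day.
params:
  # resource dynamics
  delta: 0.25       # turnover (1/day); supply rate = delta * Xi_max
  X1_max: 0.066     # primary food maximum density (mg/L)
  X2_max: 0.066     # secondary food maximum density (mg/L)
  # size thresholds
  w_min: 0.002      # access threshold for the secondary food (g), fixed
  w_A: 0.1          # maturation mass (g)
  # energetics
  kappa_e: 0.6      # assimilation efficiency
  conv: 0.001       # g dry mass per mg ingested
  rho: 0.15         # metamorphosis mortality coefficient (dies w.p. rho*theta)
  meta_loss: 0.3    # reversible-mass fraction lost at full metamorphosis
  # attack rates: A_i * spec * (w/w_opt * exp(1 - w/w_opt))^alpha
  A1_max: 30.0      # primary food, peak clearance (L/day)
  w_opt1: 0.01      # hump optimum for the primary food (g)
  alpha1: 1.0
  A2_max: 120.0     # secondary food, peak clearance (L/day)
  w_opt2: 0.05      # hump optimum for the secondary food (g)
  alpha2: 1.0
  spec_exp: 1.0     # exponent of the (1-psi)/psi specialization scaling
  # handling time H(w) = xi1 * w^-xi2 (day/mg)
  xi1: 0.019
  xi2: 0.75
  # maintenance m1 * w^m2 (g/day)
  m1: 0.01
  m2: 1.0
  # allocation
  kappa_x: 0.7      # share of somatic growth routed to irreversible mass
  kappa_rep: 0.9    # adult share of net production routed to reproduction
  # offspring cost (g of reproductive energy per offspring): c0 + c1 * w_b
  c0: 0.0004
  c1: 1.0
  # newborn condition and starvation threshold (reversible:irreversible)
  q_b: 0.2
  q_starv: 0.02
  # background mortality (1/day)
  mu_L: 0.01
  mu_J: 0.01
  mu_A: 0.01
  mu_L_extra: 0.0   # additive larval-habitat mortality (appendix scenario)
  reserves: 1
  # numerics
  h: 0.25           # base integration step (days)
  max_age: 3000.0   # integration horizon (days)
  s_eps: 1.0e-7     # survival truncation
traits0:
  psi_L: 0.0
  theta: 1.0
  w_J: 0.0115
  w_b: 0.0003
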