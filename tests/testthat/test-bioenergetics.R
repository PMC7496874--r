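p <- fx_preset()

test_that("trait validation enforces ranges and the direct-development rule", {
  expect_error(trait_vector(-0.1, 0, 0.01, 0.001), "psi_L")
  expect_error(trait_vector(0, 1.2, 0.01, 0.001), "theta")
  expect_error(trait_vector(0, 0, 1e-4, 0.001), "0.0001")
  expect_error(trait_vector(0, 0, 0.01, 5e-5), "0.0001")
  expect_false(is_direct_developer(trait_vector(0, 1, 0.01, 0.001)))
  expect_true(is_direct_developer(trait_vector(1, 0, 2e-4, 0.002)))
})

test_that("specialization profile follows the min(1, psi_L + theta) rule", {
  f <- function(psi, th) specialization_profile(
    trait_vector(psi, th, 0.01, 3e-4))
  expect_equal(f(0, 0.6), list(psi_larva = 0, psi_post = 0.6))
  expect_equal(f(0.7, 0.6), list(psi_larva = 0.7, psi_post = 1))
  expect_equal(f(1, 0), list(psi_larva = 1, psi_post = 1))
})

test_that("attack rates are gated, scaled by specialization, and hump-shaped", {
  # secondary food inaccessible below w_min regardless of specialization
  expect_equal(attack_rate(p$w_min * 0.99, 0.8, 2, p), 0)
  expect_gt(attack_rate(p$w_min * 1.01, 0.8, 2, p), 0)
  # complete specialization on one food zeroes the other's attack
  expect_equal(attack_rate(0.01, 1, 1, p), 0)
  expect_equal(attack_rate(0.01, 0, 2, p), 0)
  expect_error(attack_rate(0.01, 0.5, 3, p), "resource")
  # the maximizing mass equals the configured hump optimum (grid oracle)
  ws <- exp(seq(log(1e-4), log(1), length.out = 4001))
  a <- attack_rate(ws, 0, 1, p)
  expect_equal(ws[which.max(a)], p$w_opt1, tolerance = 1e-3)
  a2 <- attack_rate(pmax(ws, p$w_min), 1, 2, p)
  expect_equal(pmax(ws, p$w_min)[which.max(a2)], p$w_opt2, tolerance = 1e-3)
  # rises then falls with a single interior maximum
  expect_true(all(diff(a[ws < p$w_opt1]) > 0))
  expect_true(all(diff(a[ws > p$w_opt1]) < 0))
})

test_that("specialization monotonicity of attack rates", {
  for (w in c(5e-4, 5e-3, 5e-2)) {
    expect_gte(attack_rate(w, 0, 1, p), attack_rate(w, 1, 1, p))
    expect_gte(attack_rate(w, 1, 2, p), attack_rate(w, 0, 2, p))
  }
})

test_that("diet preference is encounter-proportional with defined fallbacks", {
  expect_equal(diet_preference(0.01, 0.5, 0.05, 0, p), 1)
  expect_equal(diet_preference(p$w_min / 2, 0.5, 0.05, 0.05, p), 1)
  # equal encounter rates give phi1 = 1/2
  w <- 0.01
  a1 <- attack_rate(w, 0.5, 1, p); a2 <- attack_rate(w, 0.5, 2, p)
  X2 <- 0.03
  X1 <- a2 * X2 / a1
  expect_equal(diet_preference(w, 0.5, X1, X2, p), 0.5)
  # general case matches a1 X1 / (a1 X1 + a2 X2)
  expect_equal(diet_preference(w, 0.3, 0.02, 0.05, p),
               attack_rate(w, 0.3, 1, p) * 0.02 /
                 (attack_rate(w, 0.3, 1, p) * 0.02 +
                  attack_rate(w, 0.3, 2, p) * 0.05))
})

test_that("encounter-proportional intake is near the grid-search optimum", {
  # scan preference values on a density grid: the realized intake under the
  # default rule must be within a small margin of the best fixed preference
  w <- 0.012; psi <- 0.5
  a1 <- attack_rate(w, psi, 1, p); a2 <- attack_rate(w, psi, 2, p)
  H <- handling_time(w, p)
  for (X1 in c(0.005, 0.02, 0.06)) for (X2 in c(0.005, 0.02, 0.06)) {
    phis <- seq(0, 1, length.out = 201)
    tot <- vapply(phis, function(ph) {
      e <- ph * a1 * X1 + (1 - ph) * a2 * X2
      e / (1 + H * e)
    }, numeric(1))
    ir <- intake_rates(w, psi, X1, X2, p)
    expect_gte(ir$I1 + ir$I2, 0.75 * max(tot))
  }
})

test_that("intake is saturating, bounded by 1/H, and zero without food", {
  ir0 <- intake_rates(0.01, 0.5, 0, 0, p)
  expect_equal(ir0$I1 + ir0$I2, 0)
  # saturation limit as X1 grows with X2 = 0
  irBig <- intake_rates(0.01, 0.5, 1e9, 0, p)
  expect_equal(irBig$I1, 1 / handling_time(0.01, p), tolerance = 1e-6)
  # closed form at a fixed configuration
  w <- 0.02; psi <- 0.4; X1 <- 0.03; X2 <- 0.05
  a1 <- attack_rate(w, psi, 1, p); a2 <- attack_rate(w, psi, 2, p)
  e1 <- a1 * X1; e2 <- a2 * X2
  phi1 <- e1 / (e1 + e2)
  den <- 1 + handling_time(w, p) * (phi1 * e1 + (1 - phi1) * e2)
  ir <- intake_rates(w, psi, X1, X2, p)
  expect_equal(ir$I1, phi1 * e1 / den)
  expect_equal(ir$I2, (1 - phi1) * e2 / den)
  # total intake nondecreasing in each density
  t1 <- with(intake_rates(w, psi, 0.02, 0.02, p), I1 + I2)
  t2 <- with(intake_rates(w, psi, 0.04, 0.02, p), I1 + I2)
  t3 <- with(intake_rates(w, psi, 0.04, 0.05, p), I1 + I2)
  expect_true(t1 <= t2 && t2 <= t3)
  expect_lt(t3, 1 / handling_time(w, p))
})

test_that("net production covers maintenance first and scales with kappa_e", {
  st <- individual_state(0.01, 0.004, "juvenile", 0.5)
  maint <- p$m1 * (0.014)^p$m2
  # intake exactly covering maintenance
  I_cover <- maint / (p$kappa_e * p$conv)
  expect_equal(net_production(st, I_cover, 0, p), 0)
  expect_equal(net_production(st, 0, 0, p), -maint)
  # doubling kappa_e doubles assimilation, not maintenance
  pa <- update_params(p, kappa_e = 0.3)
  pb <- update_params(p, kappa_e = 0.6)
  e1 <- net_production(st, 1, 1, pa) + maint
  e2 <- net_production(st, 1, 1, pb) + maint
  expect_equal(e2, 2 * e1)
})

test_that("allocation splits growth, routes adult share to reproduction, and
           drains reserves under starvation", {
  larva <- individual_state(0.001, 4e-4, "larva", 0)
  adult <- individual_state(0.08, 0.03, "adult", 1)
  a0 <- allocate(larva, 0, p)
  expect_equal(unlist(a0), c(dx = 0, dy = 0, E_repro = 0))
  aa <- allocate(adult, 1e-3, p)
  expect_equal(aa$E_repro, p$kappa_rep * 1e-3)
  expect_gte(aa$dx, 0); expect_gte(aa$dy, 0)
  expect_equal(aa$dx + aa$dy + aa$E_repro, 1e-3)
  for (st in list(larva, adult)) {
    neg <- allocate(st, -5e-4, p)
    expect_equal(unlist(neg), c(dx = 0, dy = -5e-4, E_repro = 0))
  }
})

test_that("fecundity follows the size-number trade-off with the prenatal
           metamorphosis surcharge", {
  tr <- trait_vector(0, 1, 0.01, 3e-4)
  expect_equal(fecundity_rate(0, tr, p), 0)
  # pre-metamorphic offspring: cost independent of theta
  tr2 <- trait_vector(0, 0.3, 0.01, 3e-4)
  expect_equal(fecundity_rate(1e-3, tr, p), fecundity_rate(1e-3, tr2, p))
  # cost strictly increasing in w_b
  trBig <- trait_vector(0, 1, 0.01, 6e-4)
  expect_gt(fecundity_rate(1e-3, tr, p), fecundity_rate(1e-3, trBig, p))
  # proportional regime: with c0 = 0 doubling w_b halves fecundity
  p0 <- update_params(p, c0 = 0)
  expect_equal(fecundity_rate(1e-3, tr, p0),
               2 * fecundity_rate(1e-3, trBig, p0))
  # direct development internalizes the metamorphosis cost linearly in theta
  dd0 <- trait_vector(1, 0, 1.1e-4, 0.002)
  dd1 <- trait_vector(1, 0.5, 1.1e-4, 0.002)
  expect_equal(fecundity_rate(1e-3, dd1, p) * (1 + p$meta_loss * 0.5),
               fecundity_rate(1e-3, dd0, p))
})

test_that("metamorphosis applies survival, reserve loss and Eq.-1 composition", {
  tr <- trait_vector(0.2, 0.6, 0.01, 3e-4)
  st <- individual_state(0.007, 0.003, "larva", 0.2)
  out <- apply_metamorphosis(st, tr, p)
  expect_equal(out$survival, 1 - p$rho * 0.6)
  expect_equal(out$state$stage, "juvenile")
  expect_equal(out$state$psi, min(1, 0.2 + 0.6))
  expect_equal(out$state$x + out$state$y,
               0.007 + 0.003 * (1 - p$meta_loss * 0.6))
  # theta = 0: stage change only
  tr0 <- trait_vector(0.2, 0, 0.01, 3e-4)
  out0 <- apply_metamorphosis(st, tr0, p)
  expect_equal(out0$survival, 1)
  expect_equal(out0$state$x + out0$state$y, 0.01)
  # survival in [0, 1] across valid configs
  for (th in seq(0, 1, by = 0.25)) {
    s <- apply_metamorphosis(st, trait_vector(0, th, 0.01, 3e-4), p)$survival
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_error(apply_metamorphosis(
    individual_state(0.01, 0.001, "adult", 1), tr, p), "larvae")
})

test_that("R rate functions agree with the C++ kernel", {
  for (case in list(c(0.001, 4e-4, 0, 0.1), c(0.01, 0.004, 1, 0.5),
                    c(0.08, 0.02, 2, 1))) {
    x <- case[1]; y <- case[2]; stg <- case[3]; psi <- case[4]
    X1 <- 0.03; X2 <- 0.02
    cpp <- ddevo:::lh_rates_cpp(x, y, as.integer(stg), psi, X1, X2,
                                unclass(p))
    stage_name <- c("larva", "juvenile", "adult")[stg + 1]
    st <- individual_state(x, y, stage_name, psi)
    ir <- intake_rates(x + y, psi, X1, X2, p)
    expect_equal(cpp$I1, ir$I1, tolerance = 1e-12)
    expect_equal(cpp$I2, ir$I2, tolerance = 1e-12)
    en <- net_production(st, ir$I1, ir$I2, p)
    expect_equal(cpp$E_net, en, tolerance = 1e-12)
    al <- allocate(st, en, p)
    expect_equal(cpp$dx, al$dx, tolerance = 1e-12)
    expect_equal(cpp$dy, al$dy, tolerance = 1e-12)
    expect_equal(cpp$E_rep, al$E_repro, tolerance = 1e-12)
  }
})
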