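p <- fx_preset()
tr <- preset_traits(p)

test_that("life history basics: no food means no reproduction; direct
           development skips the metamorphosis event", {
  lh0 <- integrate_life_history(tr, 0, 0, p)
  expect_equal(lh0$R0, 0)
  dd <- trait_vector(1, 0, 1.1e-4, 0.003)
  lh <- integrate_life_history(dd, 0.02, 0.05, p)
  expect_true(lh$direct)
  expect_equal(lh$age_meta, 0)
  expect_equal(lh$T_larva_small + lh$T_larva_large, 0)
  # with theta = 0 the newborn survival factor is 1 (no prenatal cost)
  dd1 <- trait_vector(1, 0.4, 1.1e-4, 0.003)
  lh1 <- integrate_life_history(dd1, 0.02, 0.05, p)
  expect_lt(lh1$R0, lh$R0)  # prenatal metamorphosis costs reduce R0
})

test_that("R0 agrees between step sizes (step-halving oracle)", {
  lh1 <- integrate_life_history(tr, 0.03, 0.03, p)
  p2 <- update_params(p, h = p$h / 2)
  lh2 <- integrate_life_history(tr, 0.03, 0.03, p2)
  expect_equal(lh1$R0, lh2$R0, tolerance = 1e-4)
  expect_equal(lh1$G1, lh2$G1, tolerance = 1e-3)
  expect_equal(lh1$G2, lh2$G2, tolerance = 1e-3)
})

test_that("R0 is nondecreasing in each resource density", {
  r00 <- integrate_life_history(tr, 0.02, 0.02, p)$R0
  r10 <- integrate_life_history(tr, 0.04, 0.02, p)$R0
  r11 <- integrate_life_history(tr, 0.04, 0.04, p)$R0
  expect_true(r00 <= r10 && r10 <= r11)
})

test_that("nonviable strategies return the exact trivial equilibrium", {
  p_poor <- update_params(p, X1_max = 1e-4, X2_max = 1e-4)
  eq <- solve_equilibrium(tr, p_poor)
  expect_false(eq$viable)
  expect_identical(eq$b, 0)
  expect_identical(eq$X1, p_poor$X1_max)
  expect_identical(eq$X2, p_poor$X2_max)
})

test_that("viable equilibrium satisfies R0 = 1 and resource conservation", {
  eq <- fx_equilibrium(tr, p, "eq_fat_base")
  expect_true(eq$viable)
  expect_lt(abs(eq$R0 - 1), 1e-8)
  lh <- eq$lh
  s1 <- p$delta * (p$X1_max - eq$X1)
  s2 <- p$delta * (p$X2_max - eq$X2)
  expect_lt(abs(s1 - eq$b * lh$G1) / max(s1, 1e-12), 1e-6)
  expect_lt(abs(s2 - eq$b * lh$G2) / max(s2, 1e-12), 1e-6)
  expect_true(eq$X1 <= p$X1_max && eq$X2 <= p$X2_max)
})

test_that("equilibrium is invariant under doubling max_age once survival is
           truncated", {
  eq1 <- fx_equilibrium(tr, p, "eq_fat_base")
  p2 <- update_params(p, max_age = 2 * p$max_age)
  eq2 <- solve_equilibrium(tr, p2)
  expect_equal(eq1$X1, eq2$X1, tolerance = 1e-6)
  expect_equal(eq1$X2, eq2$X2, tolerance = 1e-6)
  expect_equal(eq1$b, eq2$b, tolerance = 1e-6)
})

test_that("large-larvae fraction edge cases and quadrature oracle", {
  eq <- fx_equilibrium(tr, p, "eq_fat_base")
  dd <- trait_vector(1, 0, 1.1e-4, 0.003)
  expect_equal(large_larvae_fraction(eq, dd, p), 1)
  small <- trait_vector(0, 1, p$w_min * 0.9, 3e-4)
  expect_equal(large_larvae_fraction(eq, small, p), 0)
  # interior case: ratio of survival-weighted residence times recomputed by
  # quadrature over the recorded trajectory
  frac <- large_larvae_fraction(eq, tr, p)
  expect_gte(frac, 0); expect_lte(frac, 1)
  lh <- integrate_life_history(tr, eq$X1, eq$X2, p, trajectory = TRUE)
  tj <- lh$trajectory
  larv <- tj$stage == 0
  w <- tj$x + tj$y
  dt <- diff(c(tj$age, max(tj$age)))
  t_small <- sum((tj$S * dt)[larv & w < p$w_min])
  t_large <- sum((tj$S * dt)[larv & w >= p$w_min])
  expect_equal(frac, t_large / (t_small + t_large), tolerance = 0.02)
})

test_that("generic single-mass model variant solves too", {
  pg <- fx_preset("generic_invertebrate")
  trg <- preset_traits(pg)
  lh <- integrate_life_history(trg, pg$X1_max, pg$X2_max, pg)
  expect_gt(lh$R0, 1)
  eq <- solve_equilibrium(trg, pg)
  expect_true(eq$viable)
  expect_lt(abs(eq$R0 - 1), 1e-8)
})

test_that("parameter presets validate and reject unknown keys", {
  for (nm in c("fat_reserves", "generic_invertebrate", "toy_symmetric")) {
    pp <- make_preset(nm)
    expect_s3_class(pp, "ddevo_params")
    expect_identical(unclass(make_preset(nm))[param_names()],
                     unclass(pp)[param_names()])
  }
  expect_error(update_params(p, not_a_key = 1), "unknown parameter")
  expect_error(set_param(p, "also_wrong", 2), "unknown parameter")
  expect_equal(set_param(p, "w_min", 0.001)$w_min, 0.001)
  expect_error(update_params(p, w_min = 0.5), "w_min")
  expect_error(update_params(p, kappa_e = 0), "kappa_e")
})
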