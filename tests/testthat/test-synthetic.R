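test_that("Yule trees: cherry at n = 2, ultrametry, seed stability,
           rescaling", {
  tr <- simulate_yule_tree(2, lambda = 0.5, seed = 1)
  expect_equal(length(tr$tip.label), 2)
  depths <- ape::node.depth.edgelength(tr)[1:2]
  expect_equal(depths[1], depths[2])
  tr10 <- simulate_yule_tree(10, lambda = 0.2, seed = 5)
  expect_true(ape::is.ultrametric(tr10, tol = 1e-10))
  expect_true(ape::is.binary(tr10))
  expect_identical(ape::write.tree(simulate_yule_tree(10, 0.2, seed = 5)),
                   ape::write.tree(tr10))
  tr350 <- simulate_yule_tree(20, 0.2, seed = 2, root_age = 350)
  expect_equal(max(ape::node.depth.edgelength(tr350)), 350)
})

test_that("Yule waiting times match the pure-birth expectation", {
  # age of the root for n tips = sum over k = 2..n of Exp(lambda k) waits;
  # E = sum 1/(lambda k), Var = sum 1/(lambda k)^2
  lam <- 0.5; n <- 6; reps <- 400
  ages <- vapply(seq_len(reps), function(i)
    max(ape::node.depth.edgelength(simulate_yule_tree(n, lam, seed = i))),
    numeric(1))
  mu <- sum(1 / (lam * (2:n)))
  sdev <- sqrt(sum(1 / (lam * (2:n))^2))
  expect_lt(abs(mean(ages) - mu), 3 * sdev / sqrt(reps))
})

test_that("trait simulation: frozen chain, no dual transitions, stationarity", {
  tr <- simulate_yule_tree(60, 0.3, seed = 3, root_age = 10)
  zero <- pagel_model("dependent", setNames(rep(0, 8),
                                            pagel_rate_names("dependent")))
  d0 <- simulate_discrete_traits(tr, zero, root_state = "10",
                                 miss_D = 0, miss_E = 0, seed = 1)
  expect_true(all(d0$D == 1) && all(d0$E == 0))

  m <- random_pagel("dependent", lo = 0.1, hi = 1)
  d <- simulate_discrete_traits(tr, m, miss_D = 0, miss_E = 0, seed = 2,
                                log_events = TRUE)
  ev <- attr(d, "events")
  states <- ddevo:::state_order()
  for (r in seq_len(nrow(ev))) {
    from <- states[ev[r, "from"]]; to <- states[ev[r, "to"]]
    n_changed <- (substr(from, 1, 1) != substr(to, 1, 1)) +
                 (substr(from, 2, 2) != substr(to, 2, 2))
    expect_equal(n_changed, 1)
  }

  # high symmetric rates: joint tip frequencies near the uniform stationary
  # distribution
  fast <- pagel_model("independent",
                      c(qD01 = 3, qD10 = 3, qE01 = 3, qE10 = 3))
  big <- simulate_yule_tree(400, 0.4, seed = 6, root_age = 20)
  df <- simulate_discrete_traits(big, fast, miss_D = 0, miss_E = 0, seed = 7)
  freq <- table(factor(paste0(df$D, df$E), levels = ddevo:::state_order()))
  expect_true(all(abs(freq / 400 - 0.25) < 0.12))
})

test_that("missingness fractions follow the configured coverage", {
  tr <- simulate_yule_tree(800, 0.3, seed = 10, root_age = 50)
  m <- random_pagel("independent")
  d <- simulate_discrete_traits(tr, m, seed = 11)  # defaults 0.21 / 0.72
  expect_lt(abs(mean(is.na(d$D)) - 0.21), 0.06)
  expect_lt(abs(mean(is.na(d$E)) - 0.72), 0.06)
})

test_that("trait simulation is invariant to tip relabeling given the seed", {
  tr <- simulate_yule_tree(15, 0.3, seed = 12, root_age = 10)
  m <- random_pagel("dependent")
  d1 <- simulate_discrete_traits(tr, m, seed = 5, miss_D = 0, miss_E = 0)
  tr2 <- tr
  tr2$tip.label <- paste0("sp_", tr$tip.label)
  d2 <- simulate_discrete_traits(tr2, m, seed = 5, miss_D = 0, miss_E = 0)
  expect_identical(d1$D, d2$D)
  expect_identical(d1$E, d2$E)
})
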