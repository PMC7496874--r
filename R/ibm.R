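#' Configuration for the individual-based simulator
#'
#' @param volume habitat volume (L); multiplies densities into counts.
#' @param n0 initial number of individuals.
#' @param mut_prob per-birth, per-trait mutation probability.
#' @param mut_sd mutation-kernel standard deviations (named as the traits;
#'   absolute for `psi_L`/`theta`, relative for the masses).
#' @param decline_rate linear decline rate of `X1_max` (mg/L per day).
#' @param dt time step (days).
#' @param horizon simulated time (days).
#' @param seed integer seed (recorded in the result).
#' @param record_every store a summary row every this many days.
#' @return list of class `ibm_config`.
#' @export
ibm_config <- function(volume = 5e4, n0 = 400, mut_prob = 0.01,
                       mut_sd = c(psi_L = 0.03, theta = 0.03,
                                  w_J = 0.05, w_b = 0.05),
                       decline_rate = 0, dt = 0.5, horizon = 2000,
                       seed = 1, record_every = 10) {
  stopifnot(volume > 0, n0 > 0, mut_prob >= 0, mut_prob <= 1,
            dt > 0, horizon > 0)
  structure(list(volume = volume, n0 = n0, mut_prob = mut_prob,
                 mut_sd = mut_sd, decline_rate = decline_rate, dt = dt,
                 horizon = horizon, seed = seed,
                 record_every = record_every), class = "ibm_config")
}

#' Individual-based eco-evolutionary simulation
#'
#' Stochastic finite-population counterpart of the deterministic model:
#' individuals grow and allocate deterministically by the bioenergetic
#' rules within each time step, while deaths (background, starvation,
#' metamorphosis), reproduction and mutation are drawn stochastically at
#' step boundaries; the two food sources follow the semichemostat
#' dynamics driven by the realized consumption. `X1_max` can decline
#' linearly in time to emulate progressive degradation of the larval
#' habitat. Fully reproducible given the seed.
#'
#' @param config an [ibm_config()].
#' @param traits0 founder trait vector (all founders identical).
#' @param params parameter list (see [make_preset()]).
#' @param X_init optional initial densities (defaults to the maxima).
#' @return list of class `ibm_result`: `series` (data.frame of time,
#'   population size, resources, trait means/variances), `outcome`
#'   (`"direct-development-evolved"`, `"extinct"`, or
#'   `"metamorphosis-retained"`), `final_traits` (matrix), `seed`.
#' @export
simulate_ibm <- function(config, traits0, params, X_init = NULL) {
  stopifnot(inherits(config, "ibm_config"))
  validate_traits(traits0)
  set.seed(config$seed)
  V <- config$volume
  dt <- config$dt
  p <- params

  n <- config$n0
  # per-individual state
  tr <- matrix(rep(as.numeric(traits0[trait_names()]), each = n), n, 4,
               dimnames = list(NULL, trait_names()))
  direct0 <- traits0[["w_b"]] >= traits0[["w_J"]]
  x <- rep(traits0[["w_b"]] / (1 + p$q_b), n)
  if (p$reserves < 0.5) x <- rep(traits0[["w_b"]], n)
  y <- pmax(traits0[["w_b"]] - x, 0)
  stage <- rep(if (direct0) 1L else 0L, n)  # 0 larva, 1 juvenile, 2 adult
  psi <- rep(if (direct0) min(1, traits0[["psi_L"]] + traits0[["theta"]])
             else traits0[["psi_L"]], n)

  X1 <- if (is.null(X_init)) p$X1_max else X_init[1]
  X2 <- if (is.null(X_init)) p$X2_max else X_init[2]
  X1max_t <- p$X1_max

  lo <- trait_lower(); up <- trait_upper()
  series <- list()
  t_now <- 0
  next_rec <- 0

  while (t_now < config$horizon && n > 0) {
    w <- x + y
    # vectorized bioenergetic rates at current densities
    s1 <- (1 - psi)^p$spec_exp
    s2 <- psi^p$spec_exp
    a1 <- p$A1_max * s1 * hump_shape(w, p$w_opt1, p$alpha1)
    a2 <- ifelse(w >= p$w_min, p$A2_max * s2 * hump_shape(w, p$w_opt2, p$alpha2), 0)
    e1 <- a1 * X1; e2 <- a2 * X2
    et <- e1 + e2
    phi1 <- ifelse(et > 0, e1 / et, 1)
    H <- p$xi1 * w^-p$xi2
    den <- 1 + H * (phi1 * e1 + (1 - phi1) * e2)
    I1 <- phi1 * e1 / den
    I2 <- (1 - phi1) * e2 / den
    En <- p$kappa_e * p$conv * (I1 + I2) - p$m1 * w^p$m2

    Erep <- ifelse(stage == 2L & En > 0, p$kappa_rep * En, 0)
    G <- pmax(En, 0) - Erep
    if (p$reserves > 0.5) {
      dx <- ifelse(En >= 0, p$kappa_x * G, 0)
      dy <- ifelse(En >= 0, (1 - p$kappa_x) * G, En)
    } else {
      dx <- ifelse(En >= 0, G, En)
      dy <- 0
    }
    x <- x + dx * dt
    y <- pmax(y + dy * dt, 0)

    # resource update (explicit Euler on the semichemostat, consumption
    # evaluated at the start of the step; per-litre totals)
    X1max_t <- max(p$X1_max - config$decline_rate * t_now, 0)
    cons1 <- sum(I1) / V
    cons2 <- sum(I2) / V
    X1 <- max(X1 + (p$delta * (X1max_t - X1) - cons1) * dt, 0)
    X2 <- max(X2 + (p$delta * (p$X2_max - X2) - cons2) * dt, 0)

    # deaths: background + starvation
    mu <- ifelse(stage == 0L, p$mu_L + p$mu_L_extra,
                 ifelse(stage == 1L, p$mu_J, p$mu_A))
    dead <- runif(n) < 1 - exp(-mu * dt)
    if (p$reserves > 0.5) dead <- dead | (y < p$q_starv * x)
    else dead <- dead | (x < 0.25 * tr[, "w_b"])

    # metamorphosis and maturation events
    w <- x + y
    meta <- !dead & stage == 0L & w >= tr[, "w_J"]
    if (any(meta)) {
      th <- tr[meta, "theta"]
      die_meta <- runif(sum(meta)) < p$rho * th
      if (p$reserves > 0.5) y[meta] <- y[meta] * (1 - p$meta_loss * th)
      else x[meta] <- x[meta] * (1 - p$meta_loss * th)
      psi[meta] <- pmin(1, tr[meta, "psi_L"] + th)
      stage[meta] <- 1L
      idx_meta <- which(meta)
      dead[idx_meta[die_meta]] <- TRUE
    }
    mature <- !dead & stage == 1L & (x + y) >= p$w_A
    stage[mature] <- 2L

    # births (Poisson per adult on its reproductive energy flux)
    fert <- which(!dead & stage == 2L & Erep > 0)
    if (length(fert)) {
      cost <- (p$c0 + p$c1 * tr[fert, "w_b"]) *
        ifelse(tr[fert, "w_b"] >= tr[fert, "w_J"],
               1 + p$meta_loss * tr[fert, "theta"], 1)
      n_off <- rpois(length(fert), Erep[fert] / cost * dt)
      par_idx <- rep(fert, n_off)
      n_new <- length(par_idx)
      if (n_new > 0) {
        tr_new <- tr[par_idx, , drop = FALSE]
        # per-trait independent mutation, Gaussian, truncated to the box
        mut <- matrix(runif(n_new * 4) < config$mut_prob, n_new, 4)
        if (any(mut)) {
          sd_abs <- cbind(rep(config$mut_sd[["psi_L"]], n_new),
                          rep(config$mut_sd[["theta"]], n_new),
                          config$mut_sd[["w_J"]] * tr_new[, "w_J"],
                          config$mut_sd[["w_b"]] * tr_new[, "w_b"])
          step <- matrix(rnorm(n_new * 4), n_new, 4) * sd_abs * mut
          tr_new <- tr_new + step
          tr_new[, 1] <- pmin(pmax(tr_new[, 1], 0), 1)
          tr_new[, 2] <- pmin(pmax(tr_new[, 2], 0), 1)
          tr_new[, 3] <- pmax(tr_new[, 3], 1e-4 + 1e-9)
          tr_new[, 4] <- pmax(tr_new[, 4], 1e-4 + 1e-9)
        }
        direct_new <- tr_new[, "w_b"] >= tr_new[, "w_J"]
        # prenatal metamorphosis mortality for direct developers
        surv <- runif(n_new) >= ifelse(direct_new, p$rho * tr_new[, "theta"], 0)
        tr_new <- tr_new[surv, , drop = FALSE]
        direct_new <- direct_new[surv]
        nb <- nrow(tr_new)
        if (nb > 0) {
          xb <- if (p$reserves > 0.5) tr_new[, "w_b"] / (1 + p$q_b)
                else tr_new[, "w_b"]
          yb <- pmax(tr_new[, "w_b"] - xb, 0)
          sb <- ifelse(direct_new, 1L, 0L)
          pb <- ifelse(direct_new,
                       pmin(1, tr_new[, "psi_L"] + tr_new[, "theta"]),
                       tr_new[, "psi_L"])
          tr <- rbind(tr, tr_new)
          x <- c(x, xb); y <- c(y, yb)
          stage <- c(stage, sb); psi <- c(psi, pb)
          dead <- c(dead, rep(FALSE, nb))
        }
      }
    }

    keep <- !dead
    tr <- tr[keep, , drop = FALSE]
    x <- x[keep]; y <- y[keep]
    stage <- stage[keep]; psi <- psi[keep]
    n <- length(x)
    t_now <- t_now + dt

    if (t_now >= next_rec || n == 0) {
      series[[length(series) + 1]] <- data.frame(
        time = t_now, n = n, X1 = X1, X2 = X2, X1max = X1max_t,
        psi_L = if (n) mean(tr[, "psi_L"]) else NA_real_,
        theta = if (n) mean(tr[, "theta"]) else NA_real_,
        w_J = if (n) mean(tr[, "w_J"]) else NA_real_,
        w_b = if (n) mean(tr[, "w_b"]) else NA_real_,
        var_w_b = if (n > 1) stats::var(tr[, "w_b"]) else 0,
        frac_direct = if (n) mean(tr[, "w_b"] >= tr[, "w_J"]) else NA_real_)
      next_rec <- next_rec + config$record_every
    }
  }

  outcome <- if (n == 0) "extinct"
             else if (mean(tr[, "w_b"] >= tr[, "w_J"]) > 0.5)
               "direct-development-evolved"
             else "metamorphosis-retained"
  structure(list(series = do.call(rbind, series), outcome = outcome,
                 final_traits = tr, seed = config$seed),
            class = "ibm_result")
}

#' Replicated outcome experiment over decline rates and volumes
#'
#' Runs [simulate_ibm()] over a factorial grid of habitat-degradation
#' rates and habitat volumes with several replicates per cell, and
#' tabulates the fraction of runs per outcome with binomial (Wilson score)
#' confidence intervals.
#'
#' @param params parameter list.
#' @param traits0 founder traits.
#' @param decline_rates vector of `X1_max` decline rates (mg/L per day).
#' @param volumes vector of habitat volumes (L).
#' @param n_rep replicates per cell.
#' @param base_config an [ibm_config()] template.
#' @param seed base seed; replicate r in cell c uses distinct seeds.
#' @return data.frame with one row per (rate, volume, outcome) and the
#'   outcome fraction plus confidence bounds.
#' @export
transition_experiment <- function(params, traits0, decline_rates,
                                  volumes, n_rep = 3,
                                  base_config = ibm_config(), seed = 1) {
  stopifnot(n_rep >= 1)
  out <- list()
  cell <- 0
  for (r in decline_rates) for (V in volumes) {
    cell <- cell + 1
    flags <- character(n_rep)
    for (i in seq_len(n_rep)) {
      cfg <- base_config
      cfg$decline_rate <- r
      cfg$volume <- V
      cfg$seed <- seed + 7919 * cell + i
      flags[i] <- simulate_ibm(cfg, traits0, params)$outcome
    }
    for (o in c("direct-development-evolved", "extinct",
                "metamorphosis-retained")) {
      kk <- sum(flags == o)
      ci <- wilson_ci(kk, n_rep)
      out[[length(out) + 1]] <- data.frame(
        decline_rate = r, volume = V, outcome = o, n = n_rep, k = kk,
        fraction = kk / n_rep, lower = ci[1], upper = ci[2])
    }
  }
  do.call(rbind, out)
}

wilson_ci <- function(k, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}
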