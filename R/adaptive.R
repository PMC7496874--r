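#' Invasion fitness of a rare mutant
#'
#' Log lifetime reproduction (`log R0`) of a mutant strategy in the
#' equilibrium food environment set by the resident. At ecological
#' equilibrium this is sign-equivalent to the mutant's long-term growth
#' rate, and it vanishes for a mutant identical to the resident.
#'
#' @param mutant mutant trait vector.
#' @param resident_env a viable [solve_equilibrium()] result.
#' @param params parameter list.
#' @return invasion fitness (dimensionless).
#' @export
invasion_fitness <- function(mutant, resident_env, params) {
  validate_traits(mutant)
  if (!isTRUE(resident_env$viable))
    stop("resident environment is not viable")
  lh <- integrate_life_history(mutant, resident_env$X1, resident_env$X2, params)
  log(max(lh$R0, 1e-300))
}

# per-trait finite-difference steps: absolute for the bounded specialization
# traits, relative for the mass traits
grad_steps <- function(traits, h_rel) {
  v <- h_rel * pmax(abs(as.numeric(traits[trait_names()])), c(1, 1, 1e-3, 1e-4))
  setNames(v, trait_names())
}

#' Selection gradient
#'
#' Central-difference derivative of invasion fitness with respect to each
#' mutant trait, evaluated at the resident (so the base fitness is 0).
#' One-sided differences are used where the step would leave the trait box.
#'
#' @param resident resident trait vector (must have a viable equilibrium).
#' @param params parameter list.
#' @param h relative finite-difference step.
#' @param eq optional precomputed resident equilibrium.
#' @return named numeric 4-vector of fitness derivatives.
#' @export
selection_gradient <- function(resident, params, h = 1e-4, eq = NULL) {
  validate_traits(resident)
  if (is.null(eq)) eq <- solve_equilibrium(resident, params)
  if (!eq$viable) stop("resident has no viable equilibrium")
  tt <- as.numeric(resident[trait_names()])
  names(tt) <- trait_names()
  steps <- grad_steps(tt, h)
  lo <- trait_lower(); up <- trait_upper()
  g <- numeric(4)
  fit <- function(v) {
    tv <- tt; tv[] <- v
    invasion_fitness(structure(tv, class = "ddevo_traits"), eq, params)
  }
  for (i in seq_len(4)) {
    hi <- steps[i]
    up_ok <- tt[i] + hi <= up[i]
    lo_ok <- tt[i] - hi >= lo[i]
    if (up_ok && lo_ok) {
      tp <- tt; tp[i] <- tt[i] + hi
      tm <- tt; tm[i] <- tt[i] - hi
      g[i] <- (fit(tp) - fit(tm)) / (2 * hi)
    } else if (up_ok) {
      tp <- tt; tp[i] <- tt[i] + hi
      tp2 <- tt; tp2[i] <- tt[i] + 2 * hi
      g[i] <- (4 * fit(tp) - fit(tp2)) / (2 * hi)  # 2nd-order one-sided, f0 = 0
    } else {
      tm <- tt; tm[i] <- tt[i] - hi
      tm2 <- tt; tm2[i] <- tt[i] - 2 * hi
      g[i] <- -(4 * fit(tm) - fit(tm2)) / (2 * hi)
    }
  }
  names(g) <- trait_names()
  g
}

clip_traits <- function(tt) {
  lo <- trait_lower(); up <- trait_upper()
  tt <- pmin(pmax(tt, lo + c(0, 0, 1e-12, 1e-12)), up)
  # keep masses strictly above the admissible floor
  tt[c("w_J", "w_b")] <- pmax(tt[c("w_J", "w_b")], 1e-4 + 1e-9)
  tt
}

as_traits <- function(tt) {
  structure(tt[trait_names()], class = "ddevo_traits")
}

#' Locate an evolutionarily singular strategy
#'
#' Quasi-Newton root finding on the selection gradient, restricted to the
#' traits listed in `free` and projected onto the trait boxes. A trait
#' pinned at a box boundary with an outward-pointing gradient is treated as
#' boundary-singular (e.g. the direct-development endpoint `psi_L = 1`,
#' `theta = 0`).
#'
#' @param initial starting trait vector.
#' @param params parameter list.
#' @param free character vector of evolving traits (default all four).
#' @param tol convergence tolerance on the interior gradient components.
#' @param max_iter iteration cap.
#' @param h finite-difference step for the gradient.
#' @param quiet suppress the non-convergence trace.
#' @return list of class `ddevo_singular`: `traits`, `env` (equilibrium),
#'   `gradient`, `gradient_norm`, `pinned` (traits held at a boundary),
#'   `converged`, and `classification` (filled by [classify_singular()],
#'   `NA` here).
#' @export
find_singular <- function(initial, params, free = trait_names(),
                          tol = 1e-4, max_iter = 60, h = 1e-4,
                          quiet = FALSE) {
  validate_traits(initial)
  free <- match.arg(free, trait_names(), several.ok = TRUE)
  tt <- unclass(initial)[trait_names()]
  lo <- trait_lower(); up <- trait_upper()
  X_warm <- NULL

  # internal coordinates: identity for the bounded specialization traits,
  # log for the masses (the gradient is extremely stiff in w_J because
  # larval growth decelerates toward the metamorphosis threshold)
  to_z <- function(tt) c(tt[1], tt[2], log(tt[3]), log(tt[4]))
  from_z <- function(z) clip_traits(setNames(
    c(z[1], z[2], exp(z[3]), exp(z[4])), trait_names()))
  scale_g <- function(tt, g) g * c(1, 1, tt[3], tt[4])

  eval_grad <- function(tt) {
    eq <- solve_equilibrium(as_traits(tt), params, X_init = X_warm)
    if (!eq$viable) stop("resident not viable")
    X_warm <<- c(eq$X1, eq$X2)
    g <- selection_gradient(as_traits(tt), params, h = h, eq = eq)
    list(eq = eq, g = g, gz = scale_g(tt, g))
  }

  cliff <- character(0)  # traits pinned at a viability boundary
  pinned_of <- function(tt, g) {
    at_lo <- names(tt)[tt - lo < 1e-8 & g < 0]
    at_up <- names(tt)[tt >= up - 1e-9 & g > 0]
    union(union(intersect(c(at_lo, at_up), free), cliff),
          setdiff(trait_names(), free))
  }

  # selection may push a trait to the edge of resident viability (e.g. w_J
  # down to where post-metamorphs can no longer reach w_min): such a trait
  # is pinned at the viability cliff, not at a box boundary
  cliff_check <- function(tt, cur, act) {
    z <- to_z(tt); names(z) <- trait_names()
    found <- character(0)
    for (jt in act) {
      if (abs(cur$gz[jt]) < tol) next
      zp <- z
      zp[jt] <- z[jt] + sign(cur$gz[jt]) * 0.02
      ok <- tryCatch({
        eq <- solve_equilibrium(as_traits(from_z(zp)), params, X_init = X_warm)
        eq$viable
      }, error = function(e) FALSE)
      if (!ok) found <- c(found, jt)
    }
    found
  }

  make_result <- function(tt, cur, converged, it) {
    pin <- pinned_of(tt, cur$g)
    act <- setdiff(free, pin)
    structure(list(
      traits = as_traits(tt), env = cur$eq, gradient = cur$g,
      gradient_scaled = cur$gz,
      gradient_norm = if (length(act)) max(abs(cur$gz[act])) else 0,
      pinned = pin, converged = converged, iterations = it,
      classification = NA_character_), class = "ddevo_singular")
  }

  cur <- eval_grad(tt)
  for (it in seq_len(max_iter)) {
    pin <- pinned_of(tt, cur$g)
    act <- setdiff(free, pin)
    if (length(act) == 0 || max(abs(cur$gz[act])) < tol)
      return(make_result(tt, cur, TRUE, it))

    # finite-difference Jacobian of the scaled gradient in z on the active set
    z <- to_z(tt)
    names(z) <- trait_names()
    dz <- c(psi_L = 1e-3, theta = 1e-3, w_J = 2e-4, w_b = 2e-4)
    J <- matrix(0, length(act), length(act), dimnames = list(act, act))
    ok <- TRUE
    for (jt in act) {
      zp <- z
      zp[jt] <- z[jt] + dz[jt]
      tp <- from_z(zp)
      gp <- tryCatch(eval_grad(tp), error = function(e) NULL)
      if (is.null(gp)) { ok <- FALSE; break }
      J[, jt] <- (gp$gz[act] - cur$gz[act]) / dz[jt]
    }
    step <- if (ok) tryCatch(solve(J, -cur$gz[act]), error = function(e) NULL)
            else NULL
    if (is.null(step)) break
    # trust region in z (0.2 for psi/theta, 20% for masses); only accept
    # steps that reduce the active gradient norm
    step <- step * min(1, 0.2 / max(abs(step)))
    improved <- FALSE
    lambda <- 1
    ref <- max(abs(cur$gz[act]))
    for (ls in seq_len(10)) {
      zn <- z
      zn[act] <- z[act] + lambda * step
      tn <- from_z(zn)
      nxt <- tryCatch(eval_grad(tn), error = function(e) NULL)
      if (!is.null(nxt)) {
        actn <- setdiff(free, pinned_of(tn, nxt$g))
        newn <- if (length(actn)) max(abs(nxt$gz[actn])) else 0
        if (newn < ref) {
          tt <- tn; cur <- nxt; improved <- TRUE
          break
        }
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      new_cliff <- setdiff(cliff_check(tt, cur, act), cliff)
      if (length(new_cliff) == 0) break
      cliff <- union(cliff, new_cliff)
    }
  }
  res <- make_result(tt, cur, {
    pin <- pinned_of(tt, cur$g)
    act <- setdiff(free, pin)
    length(act) == 0 || max(abs(cur$gz[act])) < tol
  }, max_iter)
  if (!res$converged && !quiet)
    warning("find_singular did not converge; scaled gradient norm ",
            format(res$gradient_norm))
  res
}

#' Classify a singular strategy
#'
#' Evolutionary stability is read from the eigenvalues of the mutant
#' Hessian of invasion fitness (negative definite = locally uninvadable);
#' convergence stability from the eigenvalues of the Jacobian of the
#' selection gradient with respect to the resident traits, assuming an
#' identity mutational covariance (all real parts negative = attracting).
#' The combination gives: CSS (attracting, uninvadable), branching
#' (attracting, invadable), repeller (non-attracting, uninvadable) or
#' evolutionarily-unstable (neither). Traits pinned at a box boundary with
#' outward gradient are excluded from the test subspace; if all evolving
#' traits are pinned the classification is `"boundary"` (a boundary CSS).
#' Eigenvalues within `tol_eig` of zero make the verdict `"indeterminate"`.
#'
#' @param sing a `ddevo_singular` object.
#' @param params parameter list.
#' @param h finite-difference step.
#' @param tol_eig indeterminacy band for eigenvalues.
#' @return `sing` with `classification`, `hessian`, `jacobian`,
#'   `indeterminate` filled in.
#' @export
classify_singular <- function(sing, params, h = 1e-3, tol_eig = 1e-9) {
  tt <- unclass(sing$traits)[trait_names()]
  act <- setdiff(trait_names(), sing$pinned)
  if (length(act) == 0) {
    sing$classification <- "boundary"
    sing$indeterminate <- FALSE
    return(sing)
  }
  eq <- sing$env
  steps <- grad_steps(tt, h)
  lo <- trait_lower(); up <- trait_upper()

  fit <- function(tv) invasion_fitness(as_traits(clip_traits(tv)), eq, params)
  # mutant Hessian on the active subspace (f(resident) = 0)
  k <- length(act)
  H <- matrix(0, k, k, dimnames = list(act, act))
  f1 <- setNames(numeric(k), act)
  for (i in act) {
    tp <- tt; tp[i] <- tt[i] + steps[i]
    tm <- tt; tm[i] <- max(tt[i] - steps[i], lo[i])
    fp <- fit(tp); fm <- fit(tm)
    H[i, i] <- (fp + fm) / steps[i]^2  # f(resident) = 0
    f1[i] <- fp
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      a <- act[i]; b <- act[j]
      tpp <- tt; tpp[a] <- tt[a] + steps[a]; tpp[b] <- tt[b] + steps[b]
      tpm <- tt; tpm[a] <- tt[a] + steps[a]; tpm[b] <- max(tt[b] - steps[b], lo[b])
      tmp <- tt; tmp[a] <- max(tt[a] - steps[a], lo[a]); tmp[b] <- tt[b] + steps[b]
      tmm <- tt; tmm[a] <- max(tt[a] - steps[a], lo[a]); tmm[b] <- max(tt[b] - steps[b], lo[b])
      H[a, b] <- H[b, a] <-
        (fit(tpp) - fit(tpm) - fit(tmp) + fit(tmm)) / (4 * steps[a] * steps[b])
    }
  }

  # Jacobian of the selection gradient in the resident traits
  X_warm <- c(eq$X1, eq$X2)
  g0 <- sing$gradient
  Jm <- matrix(0, k, k, dimnames = list(act, act))
  for (j in act) {
    tp <- tt; tp[j] <- min(tt[j] + steps[j], up[j])
    hj <- tp[j] - tt[j]
    eqp <- solve_equilibrium(as_traits(clip_traits(tp)), params, X_init = X_warm)
    gp <- selection_gradient(as_traits(clip_traits(tp)), params, eq = eqp)
    Jm[, j] <- (gp[act] - g0[act]) / hj
  }

  ev_H <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ev_J <- eigen(Jm, only.values = TRUE)$values
  indet <- any(abs(ev_H) < tol_eig) || any(abs(Re(ev_J)) < tol_eig)
  uninvadable <- all(ev_H < 0)
  attracting <- all(Re(ev_J) < 0)
  cls <- if (attracting && uninvadable) "CSS"
         else if (attracting && !uninvadable) "branching"
         else if (!attracting && uninvadable) "repeller"
         else "evolutionarily-unstable"
  if (indet) cls <- "indeterminate"
  sing$classification <- cls
  sing$hessian <- H
  sing$jacobian <- Jm
  sing$indeterminate <- indet
  sing
}

#' Continuation of a singular strategy in a model parameter
#'
#' Tracks a singular strategy while a control parameter (typically
#' `X1_max`, so the supply rate `delta * X1_max`) is stepped from its
#' current value toward `to`. The step adapts to convergence failures;
#' when the branch can no longer be continued the terminal event is
#' bracketed by bisection and reported as
#' * `"fold"` — the singular strategy ceases to exist (the CSS meets the
#'   repeller branch),
#' * `"extinction"` — the resident equilibrium loses viability,
#' * `"range_end"` — `to` was reached.
#'
#' @param start a converged `ddevo_singular` (from [find_singular()]).
#' @param param_key name of the parameter to vary (e.g. `"X1_max"`).
#' @param to target parameter value.
#' @param params parameter list consistent with `start`.
#' @param step0 initial step (default 10% of the range).
#' @param free evolving traits (passed to [find_singular()]).
#' @param n_max maximum number of continuation points.
#' @param bracket_rel relative bracket width at which event bisection stops.
#' @param classify if `TRUE`, classify each accepted point (slower).
#' @return list of class `ddevo_continuation`: `points` (data.frame with the
#'   parameter value, traits, densities, birth rate), `terminal_event`,
#'   `bracket` (parameter values enclosing the event), `singular` (list of
#'   singular objects).
#' @export
continue_in_parameter <- function(start, param_key, to, params,
                                  step0 = NULL, free = trait_names(),
                                  n_max = 60, bracket_rel = 0.02,
                                  classify = FALSE) {
  stopifnot(inherits(start, "ddevo_singular"), isTRUE(start$converged))
  p0 <- params[[param_key]]
  if (is.null(p0)) stop("unknown parameter key: ", param_key)
  dir <- sign(to - p0)
  if (dir == 0) stop("target equals current parameter value")
  if (is.null(step0)) step0 <- abs(to - p0) / 10

  solve_at <- function(pval, init, quiet = TRUE) {
    par2 <- set_param(params, param_key, pval)
    eq_try <- tryCatch(solve_equilibrium(init, par2), error = function(e) NULL)
    if (is.null(eq_try) || !eq_try$viable)
      return(list(status = "nonviable"))
    s <- tryCatch(
      find_singular(init, par2, free = free, quiet = quiet),
      error = function(e) NULL)
    if (is.null(s) || !s$converged) return(list(status = "no_singular"))
    # guard against jumping to a distant branch
    drift <- max(abs(unclass(s$traits) - unclass(init)) /
                   pmax(abs(unclass(init)), 1e-3))
    if (drift > 1.5) return(list(status = "no_singular"))
    if (classify) {
      par_cls <- par2
      s <- classify_singular(s, par_cls)
    }
    list(status = "ok", singular = s, params = par2)
  }

  pts <- list()
  sings <- list()
  cur_par <- p0
  cur_sing <- start
  step <- step0
  terminal <- "range_end"
  fail_par <- NA_real_
  fail_status <- NA_character_

  push <- function(pval, s) {
    row <- cbind(data.frame(param = pval), equilibrium_row(s$env, s$traits))
    row$classification <- s$classification
    pts[[length(pts) + 1]] <<- row
    sings[[length(sings) + 1]] <<- s
  }
  push(cur_par, cur_sing)

  n_fail <- 0
  while (length(pts) < n_max) {
    remaining <- to - cur_par
    if (abs(remaining) < 1e-12) break
    stp <- dir * min(step, abs(remaining))
    trial <- cur_par + stp
    res <- solve_at(trial, cur_sing$traits)
    if (res$status == "ok") {
      cur_par <- trial
      cur_sing <- res$singular
      push(cur_par, cur_sing)
      step <- min(step * 1.5, step0)
      n_fail <- 0
    } else {
      n_fail <- n_fail + 1
      fail_par <- trial
      fail_status <- res$status
      step <- step / 2
      if (step < abs(to - p0) * 1e-4 || n_fail > 12) {
        # bisect the event between cur_par (good) and fail_par (bad)
        lo_ <- cur_par; hi_ <- fail_par
        last_status <- fail_status
        while (abs(hi_ - lo_) > bracket_rel * abs(lo_) + 1e-12) {
          mid <- (lo_ + hi_) / 2
          r <- solve_at(mid, cur_sing$traits)
          if (r$status == "ok") {
            lo_ <- mid; cur_par <- mid; cur_sing <- r$singular
            push(mid, r$singular)
          } else {
            hi_ <- mid; last_status <- r$status
          }
        }
        terminal <- if (last_status == "nonviable") "extinction" else "fold"
        fail_par <- hi_
        break
      }
    }
  }
  if (length(pts) >= n_max && abs(cur_par - to) > 1e-12)
    terminal <- "max_points"
  structure(list(
    points = do.call(rbind, pts),
    terminal_event = terminal,
    bracket = c(good = cur_par, bad = fail_par),
    singular = sings,
    param_key = param_key), class = "ddevo_continuation")
}

#' Canonical-equation trait trajectory
#'
#' Integrates the canonical equation of adaptive dynamics,
#' `d(traits)/dt = k * N* * g(traits)`, with identity mutational
#' covariance (all traits evolve independently), where `N*` is the total
#' equilibrium abundance of the resident and `g` the selection gradient.
#' The prefactor (mutation rate, mutational variance, the factor 1/2) is
#' folded into the single rate constant `rate`, so time is in scaled
#' evolutionary units. Traits are clipped to their boxes; the trajectory
#' is truncated with `extinct = TRUE` if the resident loses viability.
#'
#' @param initial starting trait vector.
#' @param params parameter list.
#' @param rate canonical rate constant.
#' @param horizon scaled evolutionary time horizon.
#' @param step_cap largest per-step trait change (absolute for the
#'   specialization traits, relative for the masses).
#' @param n_max maximum number of steps.
#' @return list of class `ddevo_canonical`: `trajectory` (data.frame of
#'   time, traits, densities, b), `extinct`, `final`.
#' @export
integrate_canonical <- function(initial, params, rate = 1, horizon = Inf,
                                step_cap = 0.02, n_max = 400) {
  validate_traits(initial)
  tt <- unclass(initial)[trait_names()]
  t_now <- 0
  rows <- list()
  extinct <- FALSE
  X_warm <- NULL
  for (i in seq_len(n_max)) {
    eq <- tryCatch(solve_equilibrium(as_traits(tt), params, X_init = X_warm),
                   error = function(e) NULL)
    if (is.null(eq) || !eq$viable) { extinct <- TRUE; break }
    X_warm <- c(eq$X1, eq$X2)
    g <- selection_gradient(as_traits(tt), params, eq = eq)
    N <- eq$n_larva_small + eq$n_larva_large + eq$n_juvenile + eq$n_adult
    v <- rate * N * g
    rows[[length(rows) + 1]] <- cbind(
      data.frame(time = t_now, N = N),
      equilibrium_row(eq, as_traits(tt)))
    # respect the boxes: no velocity out of a boundary
    lo <- trait_lower(); up <- trait_upper()
    v[tt <= lo + 1e-12 & v < 0] <- 0
    v[tt >= up - 1e-12 & v > 0] <- 0
    speed <- max(abs(v) / pmax(c(1, 1, abs(tt[3]), abs(tt[4])), 1e-300))
    if (speed < 1e-10 || t_now >= horizon) break
    dt <- min(step_cap / speed, horizon - t_now)
    tt <- clip_traits(tt + dt * v)
    t_now <- t_now + dt
  }
  structure(list(trajectory = do.call(rbind, rows), extinct = extinct,
                 final = as_traits(tt)), class = "ddevo_canonical")
}

#' Where can direct development evolve?
#'
#' For each combination of the access threshold `w_min` and the secondary
#' supply `delta * X2_max`, tracks the metamorphic singular strategy for
#' decreasing primary supply and records whether the branch ends in a fold
#' with a viable direct-development strategy to jump to
#' (`"direct_development"`) or at the extinction boundary
#' (`"extinction"`). Cells where the initial metamorphic strategy cannot
#' be found are recorded as `"failed"`.
#'
#' @param params parameter list (the `X1_max` in it is the starting
#'   high-supply value).
#' @param w_min_grid vector of `w_min` values (g).
#' @param X2_max_grid vector of `X2_max` values (mg/L).
#' @param start_traits initial metamorphic strategy (defaults to the
#'   preset's packaged strategy).
#' @param X1_min lowest primary-food maximum density to scan to.
#' @param free evolving traits.
#' @return data.frame with `w_min`, `X2_max`, `class`, `param_end` (the
#'   bracketed terminal `X1_max`).
#' @export
direct_development_boundary <- function(params, w_min_grid, X2_max_grid,
                                        start_traits = NULL,
                                        X1_min = 1e-3 * params$X1_max,
                                        free = trait_names()) {
  if (is.null(start_traits)) start_traits <- preset_traits(params)
  out <- list()
  for (wm in w_min_grid) for (x2 in X2_max_grid) {
    cls <- "failed"; pend <- NA_real_
    res <- tryCatch({
      par2 <- update_params(params, w_min = wm, X2_max = x2)
      # a metamorphosing population that cannot persist even at the full
      # primary supply goes extinct trivially as the supply declines
      lh0 <- integrate_life_history(start_traits, par2$X1_max, par2$X2_max,
                                    par2)
      if (!is.finite(lh0$R0) || lh0$R0 < 1) {
        cls <- "extinction"
      } else {
        s0 <- NULL
        for (wJ_try in unique(c(start_traits[["w_J"]], 0.008, 0.016, 0.005))) {
          tr_try <- start_traits
          tr_try["w_J"] <- wJ_try
          s0 <- tryCatch(find_singular(as_traits(unclass(tr_try)), par2,
                                       free = free, quiet = TRUE),
                         error = function(e) NULL)
          if (!is.null(s0) && s0$converged) break
          s0 <- NULL
        }
        if (is.null(s0)) stop("no initial singular strategy")
        cont <- continue_in_parameter(s0, "X1_max", X1_min, par2, free = free)
        pend <- unname(cont$bracket["good"])
        if (cont$terminal_event == "extinction") {
          cls <- "extinction"
        } else if (cont$terminal_event %in% c("fold", "range_end")) {
          cls <- if (dd_strategy_viable(par2, pend)) "direct_development"
                 else "extinction"
        }
      }
      TRUE
    }, error = function(e) FALSE)
    out[[length(out) + 1]] <- data.frame(w_min = wm, X2_max = x2,
                                         class = cls, param_end = pend)
  }
  do.call(rbind, out)
}

# Is there a viable direct-development strategy (psi_L = 1, theta = 0,
# offspring born past metamorphosis) at primary supply X1_max = at?
dd_strategy_viable <- function(params, at) {
  par2 <- set_param(params, "X1_max", max(at, 1e-12))
  wb0 <- max(1.5 * par2$w_min, 2e-4)
  tr <- trait_vector(psi_L = 1, theta = 0, w_J = 1.0001e-4, w_b = wb0)
  s <- tryCatch(find_singular(tr, par2, free = "w_b", quiet = TRUE),
                error = function(e) NULL)
  !is.null(s) && s$converged && s$env$viable &&
    s$traits[["w_b"]] >= s$traits[["w_J"]]
}

#' Local stability scan of the direct-development strategy
#'
#' For each primary-food maximum density, locates the direct-development
#' singular strategy (`psi_L = 1`, `theta = 0`, `w_b` evolving) and
#' reports the boundary selection gradients on `psi_L` and `theta`. The
#' strategy is locally evolutionarily stable while the `psi_L` gradient
#' points outward (nonnegative) and the `theta` gradient points outward
#' (nonpositive); the scan returns the gradients so a stability-loss
#' threshold, if any, can be bracketed.
#'
#' @param params parameter list.
#' @param X1_grid vector of `X1_max` values to scan.
#' @param wb_start starting offspring mass for the `w_b` search.
#' @return data.frame with `X1_max`, `supply`, `w_b`, `grad_psi_L`,
#'   `grad_theta`, `stable` (`NA` rows where the strategy was not found).
#' @export
dd_stability_scan <- function(params, X1_grid,
                              wb_start = max(1.5 * params$w_min, 2e-4)) {
  out <- list()
  for (x1 in X1_grid) {
    par2 <- set_param(params, "X1_max", x1)
    row <- data.frame(X1_max = x1, supply = par2$delta * x1,
                      w_b = NA_real_, grad_psi_L = NA_real_,
                      grad_theta = NA_real_, stable = NA)
    s <- tryCatch(find_singular(
      trait_vector(1, 0, 1.0001e-4, wb_start), par2, free = "w_b",
      quiet = TRUE), error = function(e) NULL)
    if (!is.null(s) && s$converged && s$env$viable) {
      g <- s$gradient
      row$w_b <- s$traits[["w_b"]]
      row$grad_psi_L <- g[["psi_L"]]
      row$grad_theta <- g[["theta"]]
      row$stable <- g[["psi_L"]] >= 0 && g[["theta"]] <= 0
    }
    out[[length(out) + 1]] <- row
  }
  do.call(rbind, out)
}
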