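#' Integrate a life history in a constant food environment
#'
#' Solves the individual-level growth, survival and reproduction
#' trajectory of a cohort with strategy `traits` in constant food densities
#' `(X1, X2)`, handling the events at `w = w_min` (secondary food becomes
#' accessible), `w = w_J` (metamorphosis; applied prenatally to the
#' newborn's survival and to the maternal offspring cost when
#' `w_b >= w_J`), and `w = w_A` (maturation). Integration uses a
#' fixed-step RK4 scheme (step `params$h` days) that lands exactly on the
#' mass thresholds, and stops when survival falls below `params$s_eps` or
#' `max_age` is reached.
#'
#' @param traits trait vector.
#' @param X1,X2 food densities (mg/L), nonnegative scalars.
#' @param params parameter list from [make_preset()].
#' @param max_age integration horizon (days); defaults to `params$max_age`.
#' @param trajectory if `TRUE`, attach the age trajectory.
#' @return a list of class `ddevo_lifehistory` with elements `R0` (expected
#'   lifetime offspring), `G1`, `G2` (expected lifetime ingestion of each
#'   food, mg per newborn), `age_meta`, `age_mature` (days, `NA` if never
#'   reached), survival-weighted stage residence times (`T_larva_small`,
#'   `T_larva_large`, `T_juvenile`, `T_adult`), `S_end`, `w_end`,
#'   `starved` and `direct`.
#' @export
integrate_life_history <- function(traits, X1, X2, params,
                                   max_age = params$max_age,
                                   trajectory = FALSE) {
  validate_traits(traits)
  stopifnot(X1 >= 0, X2 >= 0)
  out <- lh_integrate_cpp(as.numeric(traits[trait_names()]), unclass(params),
                          X1, X2, max_age, params$h, trajectory,
                          params$s_eps)
  if (!isTRUE(out$ok)) stop("life-history integration failed (non-finite state)")
  class(out) <- "ddevo_lifehistory"
  out
}

#' Resident population equilibrium
#'
#' Finds the ecological equilibrium of a resident strategy: food densities
#' `(X1*, X2*)` and population birth rate `b*` such that lifetime
#' reproduction is one (`R0(X1*, X2*) = 1`) and each semichemostat resource
#' balances, `delta * (Xi_max - Xi*) = b* * Gi(X1*, X2*)`.
#'
#' The solver exploits that R0 is increasing in each food density: writing
#' `u = b/delta`, the resource balance becomes the fixed point
#' `Xi = Xi_max - u * Gi(X1, X2)`, and R0 along that family is monotone
#' decreasing in `u`, so the nontrivial equilibrium is the unique root of
#' `log R0(u) = 0`, bracketed and polished to `|R0 - 1| < 1e-10`. If the
#' strategy cannot replace itself even with untouched food
#' (`R0(X1_max, X2_max) < 1`) the trivial consumer-free equilibrium is
#' returned with `viable = FALSE`.
#'
#' @param traits trait vector.
#' @param params parameter list.
#' @param tol convergence tolerance on `R0 - 1`.
#' @param X_init optional starting densities `c(X1, X2)` (warm start used by
#'   the continuation routines).
#' @return a list of class `ddevo_equilibrium`: `X1`, `X2`, `b`, `viable`,
#'   `R0`, stage abundances (`n_larva_small`, `n_larva_large`,
#'   `n_juvenile`, `n_adult`, per litre), and the life history `lh` at the
#'   equilibrium.
#' @export
solve_equilibrium <- function(traits, params, tol = 1e-10, X_init = NULL) {
  validate_traits(traits)
  lh_max <- integrate_life_history(traits, params$X1_max, params$X2_max, params)
  if (!is.finite(lh_max$R0) || lh_max$R0 < 1) {
    return(structure(list(
      X1 = params$X1_max, X2 = params$X2_max, b = 0, viable = FALSE,
      R0 = lh_max$R0, n_larva_small = 0, n_larva_large = 0,
      n_juvenile = 0, n_adult = 0, lh = lh_max), class = "ddevo_equilibrium"))
  }

  Xmax <- c(params$X1_max, params$X2_max)
  lh_at <- function(X) integrate_life_history(traits, X[1], X[2], params)
  used <- c(lh_max$G1 > 1e-9 * (lh_max$G1 + lh_max$G2),
            lh_max$G2 > 1e-9 * (lh_max$G1 + lh_max$G2))

  finish <- function(X, lh) {
    G <- c(lh$G1, lh$G2)
    u <- max((Xmax - X) / pmax(G, 1e-300))
    b <- params$delta * u
    structure(list(
      X1 = X[1], X2 = X[2], b = b, viable = TRUE, R0 = lh$R0,
      n_larva_small = b * lh$T_larva_small,
      n_larva_large = b * lh$T_larva_large,
      n_juvenile = b * lh$T_juvenile,
      n_adult = b * lh$T_adult,
      lh = lh), class = "ddevo_equilibrium")
  }

  if (xor(used[1], used[2])) {
    # only one resource is ever consumed: the other stays at its maximum and
    # the 1-D problem R0(X) = 1 is monotone in X
    i <- which(used)
    f1 <- function(xi) { X <- Xmax; X[i] <- xi; log(max(lh_at(X)$R0, 1e-300)) }
    root <- uniroot(f1, c(1e-12, Xmax[i]), tol = .Machine$double.eps^0.5)
    xi <- polish_1d(f1, root$root, tol)
    X <- Xmax; X[i] <- xi
    return(finish(X, lh_at(X)))
  }

  fray <- function(t) log(max(lh_at(t * Xmax)$R0, 1e-300))
  starts <- list()
  if (!is.null(X_init) && all(is.finite(X_init)) && all(X_init > 0))
    starts <- list(pmin(pmax(X_init, 1e-12), Xmax))
  t0 <- NULL
  add_ray_starts <- function() {
    # R0 = 1 along the ray X = t * Xmax (log R0 monotone in t), plus
    # asymmetric deformations of that guess as fallbacks
    t0 <<- uniroot(fray, c(1e-8, 1), tol = 1e-4)$root
    c(starts, list(t0 * Xmax,
                   c(t0^0.5, t0^1.5) * Xmax,
                   c(t0^1.5, t0^0.5) * Xmax,
                   c(t0^2, t0^0.25) * Xmax,
                   c(t0^0.25, t0^2) * Xmax))
  }
  rays_added <- length(starts) > 0
  if (length(starts) == 0) { starts <- add_ray_starts(); rays_added <- FALSE }

  # Newton with line search on F(X) = (log R0, scaled balance consistency)
  Ffun <- function(X, lh = lh_at(X)) {
    G <- c(lh$G1, lh$G2)
    sc <- max(Xmax) * max(sum(G), 1e-300)
    c(log(max(lh$R0, 1e-300)),
      ((Xmax[1] - X[1]) * G[2] - (Xmax[2] - X[2]) * G[1]) / sc)
  }
  newton_from <- function(X) {
    lh <- lh_at(X)
    Fv <- Ffun(X, lh)
    for (it in seq_len(40)) {
      if (abs(Fv[1]) < tol && abs(Fv[2]) < 1e-11) break
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        dX <- X
        hj <- max(1e-7 * Xmax[j], 1e-6 * X[j])
        dX[j] <- min(X[j] + hj, Xmax[j])
        hj <- dX[j] - X[j]
        J[, j] <- (Ffun(dX) - Fv) / hj
      }
      step <- tryCatch(solve(J, -Fv), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      improved <- FALSE
      while (lambda >= 1 / 128) {
        Xn <- pmin(pmax(X + lambda * step, 1e-12), Xmax)
        lhn <- lh_at(Xn)
        Fn <- Ffun(Xn, lhn)
        if (sum(Fn^2) < sum(Fv^2)) { improved <- TRUE; break }
        lambda <- lambda / 2
      }
      if (!improved) break
      X <- Xn; lh <- lhn; Fv <- Fn
    }
    list(X = X, lh = lh, Fv = Fv,
         ok = abs(Fv[1]) < 1e-6 && abs(Fv[2]) < 1e-8)
  }

  best <- NULL
  k <- 1
  while (k <= length(starts)) {
    res <- newton_from(starts[[k]])
    if (res$ok) { best <- res; break }
    if (is.null(best) || sum(res$Fv^2) < sum(best$Fv^2)) best <- res
    k <- k + 1
    if (k > length(starts) && rays_added) {
      rays_added <- FALSE
      n_old <- length(starts)
      starts <- add_ray_starts()
      k <- n_old + 1
    }
  }
  if (!best$ok) {
    # robust fallback: R0 is increasing in each food density, so solve
    # R0(x1(X2), X2) = 1 by a monotone inner bracket and drive the resource
    # balance residual to zero in X2 alone
    x1_of <- function(X2) {
      fi <- function(x1) log(max(lh_at(c(x1, X2))$R0, 1e-300))
      if (fi(Xmax[1]) < 0) return(NA_real_)
      r <- uniroot(fi, c(1e-12, Xmax[1]), tol = .Machine$double.eps^0.5)$root
      polish_1d(fi, r, tol)
    }
    resid <- function(X2) {
      x1 <- x1_of(X2)
      if (is.na(x1)) return(NA_real_)
      lh <- lh_at(c(x1, X2))
      (Xmax[1] - x1) * lh$G2 - (Xmax[2] - X2) * lh$G1
    }
    # lowest X2 at which the population is viable even with X1 = X1_max;
    # just above it the required x1 approaches X1_max and the residual is
    # negative, giving a guaranteed bracket if any positive residual exists
    fb <- function(X2) log(max(lh_at(c(Xmax[1], X2))$R0, 1e-300))
    X2_lo <- if (fb(1e-12 * Xmax[2]) > 0) 1e-12 * Xmax[2] else
      uniroot(fb, c(1e-12 * Xmax[2], Xmax[2]), tol = 1e-14)$root * (1 + 1e-9)
    xs <- c(X2_lo * (1 + 1e-7),
            X2_lo + (Xmax[2] - X2_lo) * seq(1e-6, 1, length.out = 30)^2)
    rs <- vapply(xs, resid, numeric(1))
    idx <- which(!is.na(rs))
    sgn <- which(diff(sign(rs[idx])) != 0)
    if (length(sgn)) {
      i1 <- idx[sgn[1]]; i2 <- idx[sgn[1] + 1]
      X2 <- uniroot(resid, c(xs[i1], xs[i2]),
                    tol = .Machine$double.eps * Xmax[2])$root
      res <- newton_from(c(x1_of(X2), X2))
      if (res$ok) best <- res
    }
  }
  if (!best$ok)
    stop("equilibrium solver did not converge (|log R0| = ",
         format(abs(best$Fv[1])), ", balance = ", format(abs(best$Fv[2])), ")")
  finish(best$X, best$lh)
}

# secant polish of a monotone scalar root to |f| < tol
polish_1d <- function(f, x, tol) {
  fx <- f(x)
  x2 <- x * (1 + 1e-6) + 1e-15
  fx2 <- f(x2)
  for (i in seq_len(40)) {
    if (abs(fx) < tol / 2 || fx2 == fx) break
    xn <- x - fx * (x2 - x) / (fx2 - fx)
    if (!is.finite(xn) || xn <= 0) break
    x2 <- x; fx2 <- fx
    x <- xn; fx <- f(x)
  }
  x
}

#' Fraction of larvae with access to the secondary food source
#'
#' At equilibrium the stable size distribution is proportional to
#' `b * S(a) da`, so stage abundances are survival-weighted residence
#' times. This returns the numerical abundance of larvae with
#' `w_min < w < w_J` divided by the abundance of all larvae (`w < w_J`).
#' Direct developers have no larvae; the fraction is then defined as 1.
#'
#' @param eq equilibrium from [solve_equilibrium()].
#' @param traits trait vector of the resident.
#' @param params parameter list.
#' @return a number in `[0, 1]`.
#' @export
large_larvae_fraction <- function(eq, traits, params) {
  if (!eq$viable) stop("equilibrium is not viable")
  if (is_direct_developer(traits)) return(1)
  if (traits[["w_J"]] <= params$w_min) return(0)
  tot <- eq$n_larva_small + eq$n_larva_large
  if (tot <= 0) return(1)
  unname(eq$n_larva_large / tot)
}

#' One-row summary of an equilibrium
#'
#' @param eq equilibrium object.
#' @param traits resident trait vector.
#' @return a one-row data.frame (traits, densities, birth rate, stage
#'   abundances) suitable for stacking into result tables.
#' @export
equilibrium_row <- function(eq, traits) {
  data.frame(psi_L = traits[["psi_L"]], theta = traits[["theta"]],
             w_J = traits[["w_J"]], w_b = traits[["w_b"]],
             X1 = eq$X1, X2 = eq$X2, b = eq$b, viable = eq$viable,
             age_meta = if (is.null(eq$lh)) NA_real_ else eq$lh$age_meta,
             n_larva_small = eq$n_larva_small,
             n_larva_large = eq$n_larva_large,
             n_juvenile = eq$n_juvenile, n_adult = eq$n_adult)
}
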