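#' Larval and post-metamorphic specialization
#'
#' Specialization on the secondary food source before and after
#' metamorphosis. Larvae express `psi_L`; post-metamorphs (juveniles and
#' adults) express `min(1, psi_L + theta)`, so the extent of metamorphosis
#' `theta` measures how much the morphology shifts at the transition.
#'
#' @param traits trait vector (see [trait_vector()]).
#' @return list with `psi_larva` and `psi_post`.
#' @export
specialization_profile <- function(traits) {
  validate_traits(traits)
  list(psi_larva = unname(traits[["psi_L"]]),
       psi_post = min(1, unname(traits[["psi_L"]]) + unname(traits[["theta"]])))
}

#' Size- and specialization-dependent attack rate
#'
#' Clearance rate (L/day) on one of the two food sources. Attack rates are
#' hump-shaped in body mass, `A_max * (w/w_opt * exp(1 - w/w_opt))^alpha`,
#' peaking at the configured optimum mass `w_opt`; their height scales with
#' the degree of specialization (`(1 - psi)^spec_exp` for the primary food,
#' `psi^spec_exp` for the secondary). The secondary food source is
#' inaccessible (attack rate exactly 0) below the body-mass threshold
#' `w_min`.
#'
#' @param w total body mass (g), positive.
#' @param psi specialization on the secondary food source, in `[0, 1]`.
#' @param resource 1 (primary) or 2 (secondary).
#' @param params parameter list, see [make_preset()].
#' @return attack rate (L/day), vectorized over `w`.
#' @export
attack_rate <- function(w, psi, resource, params) {
  if (length(resource) != 1 || !resource %in% c(1, 2))
    stop("resource must be 1 or 2")
  stopifnot(all(w > 0), psi >= 0, psi <= 1)
  if (resource == 1) {
    s <- (1 - psi)^params$spec_exp
    a <- params$A1_max * s * hump_shape(w, params$w_opt1, params$alpha1)
  } else {
    s <- psi^params$spec_exp
    a <- params$A2_max * s * hump_shape(w, params$w_opt2, params$alpha2)
    a[w < params$w_min] <- 0
  }
  a
}

hump_shape <- function(w, w_opt, alpha) {
  (w / w_opt * exp(1 - w / w_opt))^alpha
}

#' Diet preference for the primary food source
#'
#' Foraging effort allocated to the primary food source. The default rule is
#' encounter-proportional: `phi1 = A1 X1 / (A1 X1 + A2 X2)`, the
#' optimal-foraging limit for two resources with identical handling times
#' (neither resource is ever dropped from the diet). When both encounter
#' rates vanish the preference defaults to 1.
#'
#' @inheritParams attack_rate
#' @param X1,X2 resource densities (mg/L), nonnegative.
#' @return `phi1` in `[0, 1]`; `phi2 = 1 - phi1`.
#' @export
diet_preference <- function(w, psi, X1, X2, params) {
  stopifnot(X1 >= 0, X2 >= 0)
  e1 <- attack_rate(w, psi, 1, params) * X1
  e2 <- attack_rate(w, psi, 2, params) * X2
  ifelse(e1 + e2 > 0, e1 / (e1 + e2), 1)
}

#' Holling type-II intake rates
#'
#' Mass-specific ingestion (mg/day) of both food sources under a saturating
#' functional response with a handling time `H(w) = xi1 * w^-xi2` shared by
#' the two foods:
#' `I_i = phi_i A_i X_i / (1 + H(w) * sum_j phi_j A_j X_j)`.
#' Total intake is bounded by `1 / H(w)`.
#'
#' @inheritParams diet_preference
#' @return list with `I1`, `I2` (mg/day).
#' @export
intake_rates <- function(w, psi, X1, X2, params) {
  e1 <- attack_rate(w, psi, 1, params) * X1
  e2 <- attack_rate(w, psi, 2, params) * X2
  phi1 <- ifelse(e1 + e2 > 0, e1 / (e1 + e2), 1)
  phi2 <- 1 - phi1
  H <- handling_time(w, params)
  denom <- 1 + H * (phi1 * e1 + phi2 * e2)
  list(I1 = phi1 * e1 / denom, I2 = phi2 * e2 / denom)
}

#' @rdname intake_rates
#' @export
handling_time <- function(w, params) {
  params$xi1 * w^-params$xi2
}

#' Individual state
#'
#' An individual is characterized by irreversible mass `x` (bone, organs),
#' reversible mass `y` (fat, gonads), its life stage and its current
#' specialization. Total body mass is `w = x + y`.
#'
#' @param x irreversible mass (g), positive.
#' @param y reversible mass (g), nonnegative.
#' @param stage one of `"larva"`, `"juvenile"`, `"adult"`.
#' @param psi current specialization in `[0, 1]`.
#' @return a list of class `ddevo_state`.
#' @export
individual_state <- function(x, y, stage = c("larva", "juvenile", "adult"),
                             psi = 0) {
  stage <- match.arg(stage)
  stopifnot(x > 0, y >= 0, psi >= 0, psi <= 1)
  structure(list(x = x, y = y, stage = stage, psi = psi, w = x + y),
            class = "ddevo_state")
}

stage_code <- function(stage) match(stage, c("larva", "juvenile", "adult")) - 1L

#' Net biomass production
#'
#' Ingested food is assimilated with efficiency `kappa_e` and first covers
#' maintenance (`m1 * w^m2`); the remainder is the net production available
#' for growth and reproduction. Negative values indicate starvation.
#'
#' @param state an [individual_state()].
#' @param I1,I2 intake rates (mg/day).
#' @param params parameter list.
#' @return net production (g/day); may be negative.
#' @export
net_production <- function(state, I1, I2, params) {
  params$kappa_e * params$conv * (I1 + I2) -
    params$m1 * (state$x + state$y)^params$m2
}

#' Energy allocation
#'
#' Positive net production is split between irreversible and reversible mass
#' with a fixed fraction `kappa_x` to structure; adults first route a share
#' `kappa_rep` to reproduction. Negative net production drains reversible
#' mass only (irreversible mass never shrinks in the fat-reserves model).
#'
#' @param state an [individual_state()].
#' @param E_net net production (g/day).
#' @param params parameter list.
#' @return list with `dx`, `dy` (g/day) and `E_repro` (g/day).
#' @export
allocate <- function(state, E_net, params) {
  if (E_net >= 0) {
    E_rep <- if (state$stage == "adult") params$kappa_rep * E_net else 0
    G <- E_net - E_rep
    if (params$reserves > 0.5) {
      list(dx = params$kappa_x * G, dy = (1 - params$kappa_x) * G,
           E_repro = E_rep)
    } else {
      list(dx = G, dy = 0, E_repro = E_rep)
    }
  } else {
    if (params$reserves > 0.5) list(dx = 0, dy = E_net, E_repro = 0)
    else list(dx = E_net, dy = 0, E_repro = 0)
  }
}

#' Fecundity rate
#'
#' Offspring production rate of an adult. The cost of one offspring is
#' `c0 + c1 * w_b`, strictly increasing in offspring mass (the size-number
#' trade-off). When offspring are born past metamorphosis (`w_b >= w_J`)
#' the mother additionally pays for their metamorphosis and the cost is
#' multiplied by `1 + meta_loss * theta`, so fecundity declines with the
#' extent of metamorphosis.
#'
#' @param E_repro reproductive energy flux (g/day), nonnegative.
#' @param traits trait vector of the mother.
#' @param params parameter list.
#' @return fecundity (offspring/day).
#' @export
fecundity_rate <- function(E_repro, traits, params) {
  stopifnot(E_repro >= 0)
  E_repro / offspring_cost(traits, params)
}

offspring_cost <- function(traits, params) {
  base <- params$c0 + params$c1 * traits[["w_b"]]
  if (is_direct_developer(traits))
    base <- base * (1 + params$meta_loss * traits[["theta"]])
  unname(base)
}

#' Apply metamorphosis to a larva
#'
#' At the metamorphosis threshold `w = w_J` a larva becomes a juvenile: it
#' survives with probability `1 - rho * theta`, loses a fraction
#' `meta_loss * theta` of its reversible mass (of total mass in the
#' single-mass generic model), and switches specialization to
#' `min(1, psi_L + theta)`.
#'
#' @param state an [individual_state()] with `stage == "larva"`.
#' @param traits trait vector.
#' @param params parameter list.
#' @return list with `state` (the post-metamorphic juvenile) and `survival`.
#' @export
apply_metamorphosis <- function(state, traits, params) {
  if (state$stage != "larva") stop("only larvae metamorphose")
  theta <- unname(traits[["theta"]])
  survival <- 1 - params$rho * theta
  if (survival < 0) stop("invalid configuration: rho * theta exceeds 1")
  if (params$reserves > 0.5) {
    new_y <- state$y * (1 - params$meta_loss * theta)
    new_x <- state$x
  } else {
    new_x <- state$x * (1 - params$meta_loss * theta)
    new_y <- state$y
  }
  psi_post <- min(1, unname(traits[["psi_L"]]) + theta)
  list(state = individual_state(new_x, new_y, "juvenile", psi_post),
       survival = survival)
}
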