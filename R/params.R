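#' Evolving life-history traits
#'
#' Bundle the four evolving traits of a consumer strategy: larval
#' specialization on the secondary food source (`psi_L`), the extent of
#' metamorphosis (`theta`), body mass at metamorphosis (`w_J`, g) and body
#' mass at birth (`w_b`, g). Post-metamorphic specialization is always
#' `min(1, psi_L + theta)`; a strategy is a direct developer when
#' `w_b >= w_J` (metamorphosis completed before birth).
#'
#' @param psi_L larval specialization, in `[0, 1]`.
#' @param theta extent of metamorphosis, in `[0, 1]`.
#' @param w_J body mass at metamorphosis (g), `> 1e-4`.
#' @param w_b body mass at birth (g), `> 1e-4`.
#' @return a named numeric vector of class `ddevo_traits`.
#' @examples
#' tr <- trait_vector(psi_L = 0, theta = 0.6, w_J = 0.01, w_b = 4e-4)
#' specialization_profile(tr)
#' @export
trait_vector <- function(psi_L, theta, w_J, w_b) {
  tr <- c(psi_L = psi_L, theta = theta, w_J = w_J, w_b = w_b)
  validate_traits(tr)
  class(tr) <- "ddevo_traits"
  tr
}

#' @rdname trait_vector
#' @param traits a trait vector (any named numeric with the four components).
#' @export
validate_traits <- function(traits) {
  traits <- unclass(traits)
  need <- c("psi_L", "theta", "w_J", "w_b")
  if (!all(need %in% names(traits)))
    stop("traits must contain ", paste(need, collapse = ", "))
  if (any(!is.finite(traits[need])))
    stop("traits must be finite")
  if (traits[["psi_L"]] < 0 || traits[["psi_L"]] > 1)
    stop("psi_L must lie in [0, 1]")
  if (traits[["theta"]] < 0 || traits[["theta"]] > 1)
    stop("theta must lie in [0, 1]")
  if (traits[["w_J"]] <= 1e-4 || traits[["w_b"]] <= 1e-4)
    stop("w_J and w_b must be larger than 0.0001 g")
  invisible(traits[need])
}

#' Is a strategy a direct developer?
#'
#' @param traits trait vector.
#' @return `TRUE` iff `w_b >= w_J`.
#' @export
is_direct_developer <- function(traits) {
  unname(traits[["w_b"]] >= traits[["w_J"]])
}

# Canonical order and bounds of the trait box.
trait_names <- function() c("psi_L", "theta", "w_J", "w_b")
trait_lower <- function() c(psi_L = 0, theta = 0, w_J = 1e-4, w_b = 1e-4)
trait_upper <- function() c(psi_L = 1, theta = 1, w_J = Inf, w_b = Inf)

#' Load a bioenergetic parameter preset
#'
#' Returns a complete parameter set for one of the packaged model variants:
#' * `"fat_reserves"` — consumers carry irreversible (structural) and
#'   reversible (fat/gonad) mass; metamorphosis burns reserves and carries a
#'   mortality risk `rho * theta`.
#' * `"generic_invertebrate"` — a single-mass phenomenological variant in
#'   which metamorphosis shrinks body mass instead of burning reserves.
#' * `"toy_symmetric"` — two identical resources available from birth and a
#'   single effective evolving trait (`psi_L`); by symmetry its singular
#'   strategy is exactly `psi_L = 1/2`, which the adaptive-dynamics solvers
#'   are tested against.
#'
#' Presets are stored as plain-text YAML under
#' `system.file("extdata/presets", package = "ddevo")`; every parameter is
#' addressable by its key via [set_param()].
#'
#' @param name preset name.
#' @return a named list of class `ddevo_params`.
#' @examples
#' p <- make_preset("fat_reserves")
#' p$w_min
#' @export
make_preset <- function(name = c("fat_reserves", "generic_invertebrate",
                                 "toy_symmetric")) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "ddevo")
  if (path == "") stop("preset file not found for ", name)
  raw <- yaml::read_yaml(path)
  p <- structure(raw$params, preset = name, traits0 = unlist(raw$traits0),
                 class = "ddevo_params")
  validate_params(p)
  p
}

#' Default trait vector shipped with a preset
#'
#' The starting strategy packaged with each preset (a metamorphosing
#' strategy for the two full model variants).
#'
#' @param params a `ddevo_params` object.
#' @return a `ddevo_traits` vector.
#' @export
preset_traits <- function(params) {
  tr <- attr(params, "traits0")
  trait_vector(tr[["psi_L"]], tr[["theta"]], tr[["w_J"]], tr[["w_b"]])
}

param_names <- function() {
  c("delta", "X1_max", "X2_max",
    "w_min", "w_A", "kappa_e", "conv", "rho", "meta_loss",
    "A1_max", "w_opt1", "alpha1", "A2_max", "w_opt2", "alpha2", "spec_exp",
    "xi1", "xi2", "m1", "m2", "kappa_x", "kappa_rep", "c0", "c1",
    "q_b", "q_starv", "mu_L", "mu_J", "mu_A", "mu_L_extra", "reserves",
    "h", "max_age", "s_eps")
}

#' @rdname make_preset
#' @param params a parameter list to validate.
#' @export
validate_params <- function(params) {
  miss <- setdiff(param_names(), names(params))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  v <- unlist(params[param_names()])
  if (any(!is.finite(v))) stop("parameters must be finite")
  nonneg <- setdiff(param_names(), "reserves")
  if (any(v[nonneg] < 0)) stop("rates and masses must be nonnegative")
  if (params$kappa_e <= 0 || params$kappa_e > 1) stop("kappa_e must be in (0, 1]")
  if (params$rho < 0 || params$rho > 1) stop("rho must be in [0, 1]")
  if (params$meta_loss < 0 || params$meta_loss > 1) stop("meta_loss must be in [0, 1]")
  if (params$w_min >= params$w_A) stop("w_min must be below w_A")
  invisible(params)
}

#' Modify parameters by key
#'
#' Returns a copy of `params` with the named entries replaced. Unknown keys
#' are an error, so configuration typos cannot pass silently.
#'
#' @param params a `ddevo_params` object.
#' @param ... `key = value` pairs, or for [set_param()] a single key string
#'   and value.
#' @return the modified parameter list.
#' @examples
#' p <- make_preset("fat_reserves")
#' p2 <- update_params(p, X1_max = 0.05)
#' @export
update_params <- function(params, ...) {
  upd <- list(...)
  bad <- setdiff(names(upd), param_names())
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  out <- unclass(params)
  out[names(upd)] <- upd
  attributes(out) <- attributes(params)
  validate_params(out)
  out
}

#' @rdname update_params
#' @param key parameter name (string).
#' @param value new value.
#' @export
set_param <- function(params, key, value) {
  args <- stats::setNames(list(value), key)
  do.call(update_params, c(list(params), args))
}
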