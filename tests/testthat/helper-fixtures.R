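# Shared fixtures. Equilibria are memoized per session because several test
# files interrogate the same resident strategies.

.fixture_env <- new.env(parent = emptyenv())

fx_preset <- function(name = "fat_reserves") {
  key <- paste0("preset_", name)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- make_preset(name)
  .fixture_env[[key]]
}

fx_equilibrium <- function(traits, params, key) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- solve_equilibrium(traits, params)
  .fixture_env[[key]]
}

# brute-force log-likelihood by summation over all internal-node states;
# independent of the pruning implementation (uses Matrix::expm directly)
loglik_enumerate <- function(tree, data, model, root_prior = "uniform") {
  Q <- build_rate_matrix(model)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  Pk <- lapply(seq_len(nrow(tree$edge)),
               function(k) as.matrix(Matrix::expm(Q * tree$edge.length[k])))
  idx <- match(tree$tip.label, data$species)
  tipp <- t(vapply(seq_len(ntip), function(i) {
    D <- data$D[idx[i]]; E <- data$E[idx[i]]
    okD <- if (is.na(D)) c(TRUE, TRUE) else c(D == 0, D == 1)
    okE <- if (is.na(E)) c(TRUE, TRUE) else c(E == 0, E == 1)
    as.numeric(c(okD[1] & okE[1], okD[1] & okE[2],
                 okD[2] & okE[1], okD[2] & okE[2]))
  }, numeric(4)))
  pi_root <- root_prior_vector(Q, root_prior)
  combos <- as.matrix(expand.grid(rep(list(1:4), nnode)))
  total <- 0
  for (r in seq_len(nrow(combos))) {
    states <- combos[r, ]
    node_state <- function(v) if (v <= ntip) NA else states[v - ntip]
    p <- pi_root[states[1]]
    for (k in seq_len(nrow(tree$edge))) {
      par <- tree$edge[k, 1]; chd <- tree$edge[k, 2]
      sp <- node_state(par)
      if (chd <= ntip) {
        p <- p * sum(Pk[[k]][sp, ] * tipp[chd, ])
      } else {
        p <- p * Pk[[k]][sp, node_state(chd)]
      }
    }
    total <- total + p
  }
  log(total)
}

# random Pagel model with rates drawn log-uniformly
random_pagel <- function(kind, n = NULL, lo = 0.02, hi = 2) {
  rn <- pagel_rate_names(kind)
  pagel_model(kind, setNames(exp(runif(length(rn), log(lo), log(hi))), rn))
}

random_tree <- function(n_tips, seed) {
  simulate_yule_tree(n_tips, lambda = 0.3, seed = seed, root_age = 5)
}

full_traits <- function(tree, model, seed) {
  simulate_discrete_traits(tree, model, root_state = "random",
                           miss_D = 0, miss_E = 0, seed = seed)
}

as_tr <- function(v) {
  structure(v[c("psi_L", "theta", "w_J", "w_b")], class = "ddevo_traits")
}
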