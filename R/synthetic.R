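#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation of a pure-birth process: starting from two lineages,
#' waiting times between successive splits are exponential with rate
#' `lambda * k` (`k` = current number of lineages) and a uniformly chosen
#' lineage splits, until `n_tips` lineages exist; all tips are extended to
#' the final time, giving an ultrametric rooted binary tree. Optionally
#' rescaled so the root age equals `root_age`.
#'
#' @param n_tips number of tips (>= 2).
#' @param lambda speciation rate (1/Myr).
#' @param seed integer seed.
#' @param root_age if non-`NULL`, rescale depths to this root age (Myr).
#' @return an `ape::phylo` ultrametric tree with tips `t1 ... tn`.
#' @examples
#' tr <- simulate_yule_tree(10, lambda = 0.1, seed = 1)
#' @export
simulate_yule_tree <- function(n_tips, lambda = 0.1, seed = 1,
                               root_age = NULL) {
  stopifnot(n_tips >= 2, lambda > 0)
  set.seed(seed)
  # lineage ids are assigned as splits happen; tips are relabelled at the
  # end, and id 0 denotes the root joining the two initial lineages
  next_id <- 3L
  active <- c(1L, 2L)
  t_now <- 0
  node_birth <- c(0, 0)
  parent_of <- c(NA_integer_, NA_integer_)
  while (length(active) < n_tips) {
    k <- length(active)
    t_now <- t_now + rexp(1, rate = lambda * k)
    i <- active[sample.int(k, 1)]
    c1 <- next_id; c2 <- next_id + 1L
    next_id <- next_id + 2L
    parent_of[c(c1, c2)] <- i
    node_birth[c(c1, c2)] <- t_now
    active <- c(setdiff(active, i), c1, c2)
  }
  t_end <- t_now + rexp(1, rate = lambda * n_tips)

  # assemble phylo: tips = active lineages, internals = split lineages + root
  n_all <- next_id - 1L
  is_tip <- seq_len(n_all) %in% active
  tip_ids <- which(is_tip)
  int_ids <- c(0L, which(!is_tip))  # 0 is the artificial root joining 1 and 2
  tip_no <- setNames(seq_along(tip_ids), tip_ids)
  int_no <- setNames(n_tips + seq_along(int_ids), int_ids)
  node_of <- function(id) if (is_tip[id]) tip_no[[as.character(id)]] else int_no[[as.character(id)]]

  edge <- matrix(0L, 0, 2); elen <- numeric(0)
  # edges: root -> lineages 1,2; split lineage i -> children
  death <- ifelse(is_tip, t_end, NA_real_)
  for (id in seq_len(n_all)) {
    kidz <- which(parent_of == id)
    if (length(kidz)) death[id] <- node_birth[kidz[1]]
  }
  add_edge <- function(par_no, chd_no, len) {
    edge <<- rbind(edge, c(par_no, chd_no)); elen <<- c(elen, len)
  }
  for (id in 1:2)
    add_edge(int_no[["0"]], node_of(id), death[id] - 0)
  for (id in seq_len(n_all)) {
    kidz <- which(parent_of == id)
    for (ch in kidz)
      add_edge(node_of(id), node_of(ch), death[ch] - node_birth[ch])
  }
  tr <- list(edge = matrix(as.integer(edge), ncol = 2), edge.length = elen,
             tip.label = paste0("t", seq_len(n_tips)),
             Nnode = length(int_ids))
  class(tr) <- "phylo"
  tr <- ape::reorder.phylo(tr, "cladewise")
  if (!is.null(root_age)) {
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * root_age / depth
  }
  tr
}

#' Simulate two binary traits on a tree under a Pagel model
#'
#' Exact Gillespie simulation of the 4-state joint chain down every branch
#' from a root state: waiting times are exponential in the current state's
#' total leaving rate and jumps pick a single-trait transition, so the two
#' traits never change simultaneously (the structural zero of the model).
#' Missingness is applied independently per trait and tip.
#'
#' @param tree `ape::phylo` tree (branch lengths in Myr).
#' @param model generating [pagel_model()].
#' @param root_state root joint state as `"00"`, `"01"`, `"10"`, `"11"`,
#'   or `"random"` (uniform).
#' @param miss_D,miss_E per-tip missingness probabilities (defaults 0.21
#'   and 0.72, emulating 79% developmental-mode and 28% egg-size coverage
#'   in the motivating amphibian dataset).
#' @param seed integer seed.
#' @param log_events if `TRUE`, attach the per-branch event log.
#' @return data.frame `species`, `D`, `E` (with `NA` for missing), plus
#'   attributes `root_state` and (optionally) `events`.
#' @export
simulate_discrete_traits <- function(tree, model, root_state = "random",
                                     miss_D = 0.21, miss_E = 0.72,
                                     seed = 1, log_events = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  stopifnot(miss_D >= 0, miss_D < 1, miss_E >= 0, miss_E < 1)
  set.seed(seed)
  Q <- build_rate_matrix(model)
  states <- state_order()
  if (identical(root_state, "random"))
    root_state <- states[sample.int(4, 1)]
  root_idx <- match(root_state, states)
  if (is.na(root_idx)) stop("unknown root state: ", root_state)

  ntip <- length(tree$tip.label)
  node_state <- integer(ntip + tree$Nnode)
  node_state[ntip + 1L] <- root_idx
  events <- list()

  # preorder traversal so parents are assigned before children
  ord <- rev(ape::postorder(tree))
  for (k in ord) {
    par <- tree$edge[k, 1]; chd <- tree$edge[k, 2]
    s <- node_state[par]
    t_left <- tree$edge.length[k]
    repeat {
      out <- Q[s, ]; out[s] <- 0
      tot <- sum(out)
      if (tot <= 0) break
      dt <- rexp(1, tot)
      if (dt > t_left) break
      t_left <- t_left - dt
      s_new <- sample.int(4, 1, prob = out)
      if (log_events)
        events[[length(events) + 1]] <- c(edge = k, from = s, to = s_new)
      s <- s_new
    }
    node_state[chd] <- s
  }
  tip_states <- states[node_state[seq_len(ntip)]]
  D <- as.integer(substr(tip_states, 1, 1))
  E <- as.integer(substr(tip_states, 2, 2))
  D[runif(ntip) < miss_D] <- NA_integer_
  E[runif(ntip) < miss_E] <- NA_integer_
  out <- data.frame(species = tree$tip.label, D = D, E = E)
  attr(out, "root_state") <- root_state
  if (log_events)
    attr(out, "events") <- if (length(events)) do.call(rbind, events)
                           else matrix(numeric(0), 0, 3)
  out
}
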