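# Forward simulation of the episodic / environment-linked birth-death
# process.  Simulation starts with two lineages at the root and runs a
# Gillespie algorithm with piecewise-constant rates; conditioning on both
# root lineages leaving at least one sampled descendant (the same
# conditioning the likelihood uses) is implemented by rejection.

# One complete realization; returns NULL if everything dies.
sim_bd_once <- function(boundaries, lam_fwd, mu_fwd, max_lineages = 1e5) {
  T_ <- boundaries[length(boundaries)]
  k <- length(lam_fwd)
  cap <- 256L
  birth <- numeric(cap); parent <- integer(cap); endt <- numeric(cap)
  fate <- integer(cap)  # 0 = active, 1 = speciated, 2 = extinct, 3 = survived
  birth[1:2] <- 0; parent[1:2] <- 0L
  n_lin <- 2L
  active <- c(1L, 2L)
  t <- 0
  ep <- 1L
  while (length(active) > 0) {
    if (length(active) > max_lineages) {
      abort("Simulation exceeded the lineage cap; lower the rates or the root age.")
    }
    rate <- length(active) * (lam_fwd[ep] + mu_fwd[ep])
    dt <- if (rate > 0) rexp(1, rate) else Inf
    if (t + dt >= boundaries[ep + 1L]) {
      t <- boundaries[ep + 1L]
      if (ep == k) break
      ep <- ep + 1L
      next
    }
    t <- t + dt
    i <- active[sample.int(length(active), 1L)]
    if (runif(1) < lam_fwd[ep] / (lam_fwd[ep] + mu_fwd[ep])) {
      # speciation: lineage i ends, two children appear
      if (n_lin + 2L > cap) {
        cap <- cap * 2L
        length(birth) <- cap; length(parent) <- cap
        length(endt) <- cap; length(fate) <- cap
      }
      endt[i] <- t; fate[i] <- 1L
      ids <- n_lin + 1:2
      birth[ids] <- t; parent[ids] <- i; fate[ids] <- 0L
      n_lin <- n_lin + 2L
      active <- c(active[active != i], ids)
    } else {
      endt[i] <- t; fate[i] <- 2L
      active <- active[active != i]
    }
  }
  surv <- which(fate[seq_len(n_lin)] == 0L)
  endt[surv] <- T_; fate[surv] <- 3L
  list(birth = birth[seq_len(n_lin)], parent = parent[seq_len(n_lin)],
       endt = endt[seq_len(n_lin)], fate = fate[seq_len(n_lin)], T = T_)
}

# Convert a lineage record to an ape::phylo of the complete tree
# (extinct tips included, so generally non-ultrametric).  Built via a
# Newick string; recursion depth equals the number of speciations along a
# single path, which stays small for fixed-horizon simulations.
sim_to_phylo <- function(sim) {
  kids <- split(seq_along(sim$parent), sim$parent)
  len <- sim$endt - sim$birth
  nwk_of <- function(i) {
    lab <- if (sim$fate[i] == 1L) {
      ch <- kids[[as.character(i)]]
      paste0("(", nwk_of(ch[1]), ",", nwk_of(ch[2]), ")")
    } else {
      paste0(if (sim$fate[i] == 3L) "t" else "x", i)
    }
    sprintf("%s:%.17g", lab, len[i])
  }
  roots <- kids[["0"]]
  ape::read.tree(text = paste0("(", nwk_of(roots[1]), ",", nwk_of(roots[2]), ");"))
}

#' Simulate a reconstructed tree under the episodic birth-death process
#'
#' Runs the process forward from two lineages at the root over
#' piecewise-constant epoch rates, prunes extinct lineages, applies
#' uniform sampling `rho` at the present, and conditions (by rejection)
#' on both root lineages having at least one sampled descendant -- the
#' conditioning under which the likelihood is written.
#'
#' @param root_age root age in Myr (the process runs for this long).
#' @param lambda,mu per-epoch rates ordered present to past over
#'   `epochs` equal-width age intervals (scalars are recycled:
#'   constant-rate process).
#' @param epochs number of epochs (defaults to `length(lambda)`).
#' @param rho uniform sampling fraction at the present.
#' @param seed integer RNG seed (mandatory).
#' @param max_attempts rejection-sampling cap; exceeding it is an error
#'   suggesting different parameters.
#' @param max_lineages guard against runaway radiations.
#' @return A [time_tree][as_time_tree] whose `truth` attribute records
#'   the generating rates, `rho`, and the number of rejected attempts.
#' @export
simulate_tree <- function(root_age, lambda, mu, epochs = max(length(lambda), length(mu)),
                          rho = 1, seed, max_attempts = 1e4, max_lineages = 1e5) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  k <- as.integer(epochs)
  lambda <- rep_len(lambda, k); mu <- rep_len(mu, k)
  if (any(lambda < 0) || any(mu < 0)) abort("Rates must be non-negative.")
  boundaries <- seq(0, root_age, length.out = k + 1L)
  lam_fwd <- rev(lambda); mu_fwd <- rev(mu)
  attempts <- 0L
  repeat {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      abort(sprintf(
        "No accepted simulation in %d attempts; consider higher speciation rates, lower extinction, or a shorter root age.",
        as.integer(max_attempts)
      ))
    }
    sim <- sim_bd_once(boundaries, lam_fwd, mu_fwd, max_lineages)
    surv <- which(sim$fate == 3L)
    if (length(surv) < 2L) next
    sampled <- surv[runif(length(surv)) < rho]
    if (length(sampled) < 2L) next
    # both root lineages must have a sampled descendant
    root_side <- function(i) { while (sim$parent[i] != 0L) i <- sim$parent[i]; i }
    sides <- vapply(sampled, root_side, integer(1))
    if (length(unique(sides)) < 2L) next
    phy <- sim_to_phylo(sim)
    keep <- paste0("t", sampled)
    recon <- ape::keep.tip(phy, keep)
    out <- as_time_tree(recon, tol = 1e-6)
    attr(out, "truth") <- list(
      lambda = lambda, mu = mu, rho = rho, epochs = k,
      root_age = root_age, n_survivors = length(surv),
      attempts = attempts, seed = seed
    )
    return(out)
  }
}

#' Forward-simulated reconstructed branching times
#'
#' Repeatedly simulates the process forward and returns only the
#' speciation times that survive reconstruction (both daughter lineages
#' leave a sampled descendant), pooled across accepted replicates that
#' meet the root-survival conditioning.  This is the cheap Monte-Carlo
#' counterpart of [speciation_time_cdf()]: the pooled times are draws
#' from that distribution function.
#'
#' @inheritParams simulate_tree
#' @param reps number of accepted replicates to pool.
#' @return Numeric vector of forward-time speciation times (0 = root).
#' @export
simulate_branching_times <- function(root_age, lambda, mu,
                                     epochs = max(length(lambda), length(mu)),
                                     rho = 1, reps = 1000, seed,
                                     max_attempts = 100 * reps) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  k <- as.integer(epochs)
  boundaries <- seq(0, root_age, length.out = k + 1L)
  lam_fwd <- rev(rep_len(lambda, k)); mu_fwd <- rev(rep_len(mu, k))
  out <- vector("list", reps)
  got <- 0L
  attempts <- 0L
  while (got < reps) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) abort("Too many rejected simulations; adjust the rates.")
    sim <- sim_bd_once(boundaries, lam_fwd, mu_fwd)
    n_lin <- length(sim$fate)
    has <- sim$fate == 3L & runif(n_lin) < rho
    if (n_lin > 2L) {
      for (i in seq(n_lin, 3L)) if (has[i]) has[sim$parent[i]] <- TRUE
    }
    if (!(has[1L] && has[2L])) next
    got <- got + 1L
    spec <- which(sim$fate == 1L)
    if (length(spec) > 0L) {
      # children have consecutive ids; count has-descendant children per parent
      n_has_kids <- tabulate(sim$parent[has & sim$parent > 0L], nbins = n_lin)
      out[[got]] <- sim$endt[spec[n_has_kids[spec] == 2L]]
    }
  }
  unlist(out)
}

#' Draw an environment-linked rate trajectory and simulate a tree
#'
#' Generates per-epoch log rates from the chosen environmentally
#' dependent model (`gmrf`: trend plus Brownian increments; `ucln`:
#' trend plus iid deviations; `fixed`: the deterministic trend) and
#' simulates a reconstructed tree under them.
#'
#' @param env raw environmental series (`age_mya`, `value`).
#' @param root_age,epochs,rho,seed,max_attempts as in [simulate_tree()].
#' @param lambda0,mu0 present-day rates.
#' @param beta correlation factor applied to both rates.
#' @param sigma independent rate variation (0 = `fixed` linkage).
#' @param model `"gmrf"`, `"ucln"`, or `"fixed"`.
#' @return A [time_tree][as_time_tree]; its `truth` attribute records
#'   the realized trajectories, `beta`, `sigma`, and the binned deltas.
#' @export
simulate_env_tree <- function(env, root_age, epochs, lambda0, mu0, beta,
                              sigma = 0, model = c("gmrf", "ucln", "fixed"),
                              rho = 1, seed, max_attempts = 1e4) {
  model <- match.arg(model)
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  k <- as.integer(epochs)
  binned <- bin_environment(env, seq(0, root_age, length.out = k + 1L))
  delta <- env_deltas(binned)
  traj <- function(rate0) {
    base <- log(fixed_env_rates(rate0, beta, delta))
    noise <- if (sigma == 0 || model == "fixed") {
      rep(0, k)
    } else if (model == "ucln") {
      rnorm(k, 0, sigma)
    } else {
      c(0, cumsum(rnorm(k - 1L, 0, sigma)))
    }
    exp(base + noise)
  }
  lambda <- traj(lambda0)
  mu <- traj(mu0)
  tree <- simulate_tree(root_age, lambda, mu, epochs = k, rho = rho,
                        seed = sample.int(.Machine$integer.max, 1L),
                        max_attempts = max_attempts)
  truth <- attr(tree, "truth")
  truth$beta <- beta; truth$sigma <- sigma; truth$model <- model
  truth$delta <- delta; truth$lambda0 <- lambda0; truth$mu0 <- mu0
  attr(tree, "truth") <- truth
  tree
}

#' Uniformly subsample the tips of a tree
#'
#' Each tip is kept independently with probability `rho`; if fewer than
#' two tips survive the draw is retried with a fresh stream (reported via
#' a message).
#'
#' @param tree a [time_tree][as_time_tree].
#' @param rho per-tip retention probability in (0, 1].
#' @param seed integer RNG seed.
#' @param max_retries retry cap.
#' @return A [time_tree][as_time_tree] on the retained tips; its
#'   `kept_tips` attribute lists them.
#' @export
prune_uniform <- function(tree, rho, seed, max_retries = 100L) {
  stopifnot(inherits(tree, "time_tree"))
  if (rho <= 0 || rho > 1) abort("`rho` must lie in (0, 1].")
  set.seed(seed)
  if (rho == 1) {
    out <- tree
    attr(out, "kept_tips") <- tree$phylo$tip.label
    return(out)
  }
  for (i in seq_len(max_retries)) {
    keep <- tree$phylo$tip.label[runif(tree$n_tips) < rho]
    if (length(keep) >= 2L) {
      if (i > 1L) inform(sprintf("prune_uniform: %d retries before >= 2 tips survived.", i - 1L))
      out <- as_time_tree(ape::keep.tip(tree$phylo, keep))
      attr(out, "kept_tips") <- keep
      return(out)
    }
  }
  abort("Fewer than 2 tips survived uniform sampling after all retries.")
}

# Draw iid speciation times from the grid's distribution function by
# numerical inversion.
draw_speciation_times <- function(grid, n) {
  T_ <- grid$boundaries[grid$k + 1L]
  tg <- seq(grid$boundaries[1], T_, length.out = 2048L)
  Fg <- speciation_time_cdf(grid, tg)
  inv <- approxfun(Fg / Fg[length(Fg)], tg, ties = "ordered", rule = 2)
  pmin(inv(runif(n)), T_ * (1 - 1e-9))
}

# Assign sorted times to the internal nodes of a topology along a
# uniformly random ranked history.  `kids_int` maps each internal node to
# its internal-node children; a node becomes available once its parent
# has a time, and is picked with probability proportional to the number
# of internal nodes in its subtree (which makes the ranking uniform over
# all rankings compatible with the topology).
assign_ranked_times <- function(root_children, kids_int, sub_size, ts) {
  node_time <- setNames(numeric(0), character(0))
  avail <- root_children
  out <- integer(length(ts))
  for (j in seq_along(ts)) {
    w <- sub_size[avail]
    pick <- avail[sample.int(length(avail), 1L, prob = w)]
    out[j] <- pick
    avail <- c(avail[avail != pick], kids_int[[pick]])
  }
  out
}

# Number of internal nodes in each internal node's subtree (itself
# included), by an iterative postorder sweep.
internal_subtree_sizes <- function(kids_int, root, n_all) {
  sub_size <- integer(n_all)
  stack <- root
  order_out <- integer(0)
  while (length(stack) > 0) {
    v <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    order_out <- c(order_out, v)
    stack <- c(stack, kids_int[[v]])
  }
  for (v in rev(order_out)) {
    sub_size[v] <- 1L + sum(sub_size[kids_int[[v]]])
  }
  sub_size
}

# Redraw all non-root divergence times of a phylo from the
# speciation-time distribution of the given grid (root age fixed).
redraw_divergence_times <- function(phy, grid) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  n_node <- phy$Nnode
  T_ <- grid$boundaries[grid$k + 1L]
  ts <- sort(draw_speciation_times(grid, n_node - 1L))
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  n_all <- n + n_node
  kids_int <- vector("list", n_all)
  for (v in (n + 1L):n_all) {
    ch <- kids[[as.character(v)]]
    kids_int[[v]] <- ch[ch > n]
  }
  sub_size <- internal_subtree_sizes(kids_int, root, n_all)
  node_time <- rep(NA_real_, n_all)
  node_time[root] <- 0
  node_time[seq_len(n)] <- T_
  picks <- assign_ranked_times(kids_int[[root]], kids_int, sub_size, ts)
  node_time[picks] <- ts
  phy$edge.length <- node_time[phy$edge[, 2]] - node_time[phy$edge[, 1]]
  phy
}

#' Simulate a tree under empirical (clade-informed) taxon sampling
#'
#' Emulates incomplete sampling with known per-clade missing counts: the
#' missing species are attached uniformly at random within their named
#' clade (as sister to a random clade member), all divergence times are
#' redrawn from the chosen process conditional on the topology and root
#' age, and the added species are then pruned away.  The returned tree
#' has the base topology with fresh node ages; the clade table is
#' re-resolved against it.
#'
#' @param base_tree a [time_tree][as_time_tree] (the "observed" taxa).
#' @param clades clade table with missing counts (resolved or not).
#' @param lambda,mu rates, present to past over `epochs` equal-width age
#'   epochs (scalars = constant-rate process).
#' @param epochs number of epochs for the generating process.
#' @param seed integer RNG seed.
#' @return A list with elements `tree` (the pruned, re-dated
#'   [time_tree][as_time_tree]) and `clades` (the table resolved against
#'   it).
#' @export
simulate_empirical_sampling <- function(base_tree, clades, lambda, mu,
                                        epochs = max(length(lambda), length(mu)),
                                        seed) {
  if (missing(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  stopifnot(inherits(base_tree, "time_tree"))
  cl <- validate_resolved_clades(clades, base_tree)
  phy <- base_tree$phylo
  n <- base_tree$n_tips
  n_all_base <- n + phy$Nnode
  root <- n + 1L

  # augmented topology on parent/children arrays; new node ids appended
  # after the base ids, so the base topology is untouched
  parent <- integer(n_all_base)
  kids <- vector("list", n_all_base)
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    parent[ch] <- p
    kids[[p]] <- c(kids[[p]], ch)
  }
  next_id <- n_all_base
  for (i in seq_len(nrow(cl))) {
    ki <- cl$missing[i]
    if (ki == 0L) next
    members <- phangorn_free_descendants(phy, cl$mrca_node[i])
    if (length(members) < 2L) abort("Clade with missing species has fewer than two sampled members.")
    for (j in seq_len(ki)) {
      host <- members[sample.int(length(members), 1L)]
      new_int <- next_id + 1L
      new_tip <- next_id + 2L
      next_id <- next_id + 2L
      length(parent) <- next_id
      length(kids) <- next_id
      p <- parent[host]
      kids[[p]][kids[[p]] == host] <- new_int
      kids[[new_int]] <- c(host, new_tip)
      parent[host] <- new_int
      parent[new_int] <- p
      parent[new_tip] <- new_int
      members <- c(members, new_tip)
    }
  }

  # redraw every non-root divergence time of the augmented tree from the
  # speciation-time distribution of the generating process
  k <- as.integer(epochs)
  grid <- epoch_grid_ages(base_tree$root_age, k,
                          rep_len(lambda, k), rep_len(mu, k), rho = 1)
  n_aug <- next_id
  is_internal <- lengths(kids) > 0L
  kids_int <- lapply(kids, function(ch) ch[is_internal[ch]])
  sub_size <- internal_subtree_sizes(kids_int, root, n_aug)
  ts <- sort(draw_speciation_times(grid, sum(is_internal) - 1L))
  node_time <- rep(NA_real_, n_aug)
  node_time[root] <- 0
  picks <- assign_ranked_times(kids_int[[root]], kids_int, sub_size, ts)
  node_time[picks] <- ts

  # prune back to the base taxa: the base topology is unchanged, only its
  # node times are replaced
  T_ <- base_tree$root_age
  node_time[!is_internal] <- T_
  out_phy <- phy
  out_phy$edge.length <- node_time[phy$edge[, 2]] - node_time[phy$edge[, 1]]
  tree <- as_time_tree(out_phy)
  list(tree = tree,
       clades = resolve_clades(tree, cl[c("clade", "taxonA", "taxonB", "missing")]))
}

# tip indices below node v without depending on phangorn
phangorn_free_descendants <- function(phy, v) {
  n <- ape::Ntip(phy)
  if (v <= n) return(v)
  out <- integer(0)
  stack <- v
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  while (length(stack) > 0) {
    x <- stack[[1]]; stack <- stack[-1]
    ch <- kids[[as.character(x)]]
    tips <- ch[ch <= n]
    out <- c(out, tips)
    stack <- c(stack, ch[ch > n])
  }
  sort(out)
}

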