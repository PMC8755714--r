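# Episodic birth-death likelihood machinery.
#
# All computation is carried out in log space.  The central quantities are,
# for a lineage alive at forward time t (0 = root, T = present):
#
#   r(t, T)  = integral over [t, T] of (mu(s) - lambda(s)) ds
#   P(t)     = P(N(T) > 0 | N(t) = 1), survival to the present including
#              sampling with probability rho
#   q(t)     = P(t) * exp(r(t, T))
#   p1(t)    = P(t)^2 * exp(r(t, T)) / rho, the probability that a lineage
#              at t leaves exactly one sampled descendant
#
# For piecewise-constant rates, 1 / P(t) has the closed form
#   exp(r(t, T)) / rho + sum_j lambda_j * exp(r(t, a_j)) * g_j
# with g_j = (exp(r_j * dt_j) - 1) / r_j over the epochs intersecting
# [t, T]; every term is positive, so the sum is accumulated by
# log-sum-exp and no intermediate can overflow or produce NaN, including
# the lambda = mu degeneracy which switches to a series expansion.

# threshold below which |mu - lambda| is treated as critical (lambda = mu)
.BD_RATE_TOL <- 1e-10

logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  both_ninf <- is.infinite(m) & m < 0
  out[both_ninf] <- -Inf
  out
}

# log((exp(r * d) - 1) / r), stable for r of either sign and r ~ 0; d >= 0.
log_expm1_ratio <- function(r, d) {
  nn <- max(length(r), length(d))
  r <- rep_len(r, nn)
  d <- rep_len(d, nn)
  rd <- r * d
  out <- numeric(nn)
  pos <- r > .BD_RATE_TOL
  neg <- r < -.BD_RATE_TOL
  mid <- !pos & !neg
  out[pos] <- rd[pos] + log1p(-exp(-rd[pos])) - log(r[pos])
  out[neg] <- log1p(-exp(rd[neg])) - log(-r[neg])
  # second-order series: (e^{rd}-1)/r = d (1 + rd/2 + (rd)^2/6 + ...)
  out[mid] <- log(d[mid]) + log1p(rd[mid] / 2 + rd[mid]^2 / 6)
  out[d == 0] <- -Inf
  out
}

# Per-parameter constants reused by every evaluation on the same grid.
bd_constants <- function(boundaries, lambda, mu, rho) {
  k <- length(boundaries) - 1L
  dx <- diff(boundaries)
  r_ep <- mu - lambda
  Rcum <- c(0, cumsum(r_ep * dx))          # Rcum[i] = r(0, boundaries[i])
  log_g <- log_expm1_ratio(r_ep, dx)
  loglam <- log(lambda)
  logS <- numeric(k)                        # suffix sums anchored at t = 0
  logS[k] <- Rcum[k + 1L] - log(rho)
  if (k > 1L) {
    for (e in seq(k - 1L, 1L)) {
      logS[e] <- logaddexp(logS[e + 1L], loglam[e + 1L] + Rcum[e + 1L] + log_g[e + 1L])
    }
  }
  list(
    x = boundaries, k = k, lambda = lambda, mu = mu, rho = rho,
    r_ep = r_ep, Rcum = Rcum, loglam = loglam, logS = logS,
    rTtot = Rcum[k + 1L]
  )
}

bd_epoch_of <- function(t, cst) {
  e <- findInterval(t, cst$x, rightmost.closed = TRUE)
  pmin(pmax(e, 1L), cst$k)
}

# r(0, t), vectorized
bd_r0 <- function(t, cst, e = bd_epoch_of(t, cst)) {
  cst$Rcum[e] + cst$r_ep[e] * (t - cst$x[e])
}

# log(1 / P(t)), vectorized over forward times t
bd_log_inv_P <- function(t, cst) {
  e <- bd_epoch_of(t, cst)
  r0t <- bd_r0(t, cst, e)
  term_tail <- -r0t + cst$logS[e]
  term_here <- cst$loglam[e] + log_expm1_ratio(cst$r_ep[e], cst$x[e + 1L] - t)
  logaddexp(term_tail, term_here)
}

# log(1 - q(t)) with q(t) = P(t) exp(r(t, T)); q <= rho <= 1.
bd_log_one_minus_q <- function(t, cst) {
  logq <- -bd_log_inv_P(t, cst) + (cst$rTtot - bd_r0(t, cst))
  logq <- pmin(logq, 0)
  ifelse(logq == 0, -Inf, log(-expm1(logq)))
}

check_grid_time <- function(grid, t, what = "t") {
  lo <- grid$boundaries[1]
  hi <- grid$boundaries[grid$k + 1L]
  if (any(t < lo - 1e-9 | t > hi + 1e-9)) {
    abort(sprintf("`%s` must lie within the grid span [%g, %g].", what, lo, hi))
  }
  pmin(pmax(t, lo), hi)
}

#' Net diversification exponent over an interval
#'
#' The integral of `mu(s) - lambda(s)` over `[t_from, t_to]` in forward
#' time.  This exponent governs the deterministic decay of the expected
#' reconstructed lineage count and is additive over contiguous intervals.
#'
#' @param grid an [epoch_grid()].
#' @param t_from,t_to forward times within the grid span, `t_from <= t_to`.
#' @return A scalar (or vector, if the inputs are vectors) value of the
#'   rate integral.
#' @export
net_rate_exponent <- function(grid, t_from, t_to) {
  stopifnot(inherits(grid, "epoch_grid"))
  t_from <- check_grid_time(grid, t_from, "t_from")
  t_to <- check_grid_time(grid, t_to, "t_to")
  if (any(t_to < t_from)) abort("`t_to` must not precede `t_from`.")
  cst <- bd_constants(grid$boundaries, grid$lambda, grid$mu, grid$rho)
  bd_r0(t_to, cst) - bd_r0(t_from, cst)
}

#' Probability that a lineage survives to the present and is sampled
#'
#' `P(N(T) > 0 | N(t_start) = 1)` under the episodic birth-death process,
#' including sampling of extant descendants with probability `rho`.  At
#' `t_start = T` only the sampling step remains, so the value is `rho`.
#'
#' @param grid an [epoch_grid()].
#' @param t_start forward time(s) within the grid span.
#' @return Survival probabilities in (0, 1].
#' @export
survival_probability <- function(grid, t_start) {
  stopifnot(inherits(grid, "epoch_grid"))
  t_start <- check_grid_time(grid, t_start, "t_start")
  cst <- bd_constants(grid$boundaries, grid$lambda, grid$mu, grid$rho)
  out <- exp(-bd_log_inv_P(t_start, cst))
  # at the present only the sampling step remains; return rho exactly
  out[t_start == grid$boundaries[grid$k + 1L]] <- grid$rho
  out
}

#' Distribution function of a reconstructed speciation time
#'
#' Cumulative distribution function of the time of a speciation event on a
#' surviving lineage, conditioned to lie in the window from the root
#' (`t1`, the first grid boundary) to the present `T`:
#' `F(t_c) = 1 - (1 - q(t_c)) / (1 - q(t1))` with
#' `q(t) = P(t) exp(r(t, T))`.  `F(t1) = 0`, `F` is non-decreasing, and
#' `F(T) = 1` under complete sampling.
#'
#' @param grid an [epoch_grid()].
#' @param t_c forward time(s) within the grid span.
#' @return Probabilities in `[0, 1]`.
#' @export
speciation_time_cdf <- function(grid, t_c) {
  stopifnot(inherits(grid, "epoch_grid"))
  t_c <- check_grid_time(grid, t_c, "t_c")
  cst <- bd_constants(grid$boundaries, grid$lambda, grid$mu, grid$rho)
  l1q_root <- bd_log_one_minus_q(grid$boundaries[1], cst)
  l1q <- bd_log_one_minus_q(t_c, cst)
  pmin(pmax(1 - exp(l1q - l1q_root), 0), 1)
}

# Static per-tree quantities shared by all likelihood evaluations.
tree_lik_data <- function(tree) {
  stopifnot(inherits(tree, "time_tree"))
  n <- tree$n_tips
  node_ages <- branching_ages(tree, drop_root = FALSE)
  list(
    n = n,
    root_age = tree$root_age,
    # forward times of the non-root internal nodes
    t_nodes = tree$root_age - node_ages[-1L]
  )
}

check_grid_tree <- function(grid, root_age) {
  ok <- abs(grid$boundaries[1]) <= 1e-8 * root_age &&
    abs(grid$boundaries[grid$k + 1L] - root_age) <= 1e-6 * root_age
  if (!ok) {
    abort(sprintf(
      "Grid must span forward time [0, %g] (root to present); got [%g, %g].",
      root_age, grid$boundaries[1], grid$boundaries[grid$k + 1L]
    ))
  }
}

# Core log density given precomputed tree data; conditions on two root
# lineages at t1 = 0 both surviving to the present.
bd_tree_log_density <- function(td, cst) {
  log_P_root <- -bd_log_inv_P(cst$x[1], cst)
  # log p1(t) = 2 log P(t) + r(t, T) - log rho
  e <- bd_epoch_of(td$t_nodes, cst)
  logP <- -bd_log_inv_P(td$t_nodes, cst)
  log_p1 <- 2 * logP + (cst$rTtot - bd_r0(td$t_nodes, cst, e)) - log(cst$rho)
  out <- (td$n - 1) * log(2) - lgamma(td$n + 1) +
    2 * (log_P_root + cst$rTtot - log(cst$rho)) +
    sum(cst$loglam[e] + log_p1)
  if (is.nan(out)) -Inf else out
}

#' Log probability density of a reconstructed tree
#'
#' Density of an ultrametric reconstructed tree under the episodic
#' birth-death process with uniform taxon sampling `rho`, conditioned on
#' two lineages at the root and on both root lineages surviving to the
#' present.  Includes the `2^(n-1) / n!` labeled-history constant.
#'
#' @param tree a [time_tree][as_time_tree].
#' @param grid an [epoch_grid()] spanning forward time `[0, root_age]`.
#' @return The log density (a finite scalar).
#' @export
tree_log_density <- function(tree, grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  td <- tree_lik_data(tree)
  check_grid_tree(grid, td$root_age)
  cst <- bd_constants(grid$boundaries, grid$lambda, grid$mu, grid$rho)
  bd_tree_log_density(td, cst)
}

# Per-clade factor: each of the k_i missing speciation events is known to
# have occurred after the clade age c_i; under the window-[t1, T] CDF F of
# speciation_time_cdf this contributes (1 - F(c_i))^{k_i}.
bd_missing_clade_terms <- function(cst, c_fwd, k_missing, m, n) {
  l1q_root <- bd_log_one_minus_q(cst$x[1], cst)
  l1q <- bd_log_one_minus_q(c_fwd, cst)
  lgamma(m) - lgamma(n) +
    sum(k_missing * (l1q - l1q_root) - lgamma(k_missing + 1))
}

#' Joint log density under empirical (clade-informed) taxon sampling
#'
#' Extends [tree_log_density()] to incomplete sampling where the number of
#' missing species is known per named clade.  The tree factor is evaluated
#' at `rho = 1` (the missing species are accounted for by the clade terms;
#' combining a global `rho < 1` with clade terms would double-count) and
#' each of the `k_i` missing speciation times is integrated over the
#' interval from the clade age to the present via the speciation-time
#' distribution function, contributing
#' `(m-1)!/(n-1)! * prod_i (1 - F(c_i))^{k_i} / k_i!`.
#' All factorials are computed as log-gamma differences.
#'
#' @param tree a [time_tree][as_time_tree].
#' @param grid an [epoch_grid()] with `rho = 1`.
#' @param clades a clade table resolved against `tree` by
#'   [resolve_clades()].
#' @param clade_age use the clade's `"crown"` age (default: the MRCA of
#'   its sampled members) or its `"stem"` age as the lower bound of the
#'   missing-speciation window.
#' @return The joint log density (a finite scalar).
#' @export
empirical_sampling_log_density <- function(tree, grid, clades,
                                           clade_age = c("crown", "stem")) {
  clade_age <- match.arg(clade_age)
  stopifnot(inherits(grid, "epoch_grid"))
  if (grid$rho != 1) {
    abort("Empirical taxon sampling requires `rho = 1` in the grid; missing species are modeled by the clade terms.")
  }
  td <- tree_lik_data(tree)
  check_grid_tree(grid, td$root_age)
  cl <- validate_resolved_clades(clades, tree)
  age_col <- if (clade_age == "crown") cl$mrca_age else cl$stem_age
  if (any(age_col > td$root_age + 1e-9)) {
    abort("Clade age exceeds the root age of the tree.")
  }
  m <- attr(cl, "m_total")
  cst <- bd_constants(grid$boundaries, grid$lambda, grid$mu, grid$rho)
  bd_tree_log_density(td, cst) +
    bd_missing_clade_terms(cst, td$root_age - age_col, cl$missing, m, td$n)
}
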