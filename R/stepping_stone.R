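#' Stepping-stone estimate of the log marginal likelihood
#'
#' Runs a ladder of power posteriors `prior * likelihood^b` with
#' exponents placed at quantiles of a Beta(0.3, 1) distribution (dense
#' near the prior, the standard stepping-stone placement) and accumulates
#' the marginal likelihood as the product of importance-sampling ratios
#' between adjacent stones.  Each stone is its own MCMC run warm-started
#' from the previous stone.
#'
#' @param model an [mcmc_model()].
#' @param stones number of stones (power-posterior levels, >= 2;
#'   128 in the full analyses).
#' @param iters MCMC sweeps per stone (default 2000).
#' @param burnin_frac fraction of each stone's sweeps discarded.
#' @param seed integer RNG seed; the estimate is deterministic given the
#'   seed.
#' @param alpha shape of the Beta(alpha, 1) exponent placement.
#' @param verbose report per-stone progress?
#' @return An object of class `evidence_estimate`: a list with
#'   `log_marginal`, `stone_table` (a tibble of exponents, per-stone mean
#'   log likelihood, and log-ratio contributions), `stones`, `seed`.
#' @export
stepping_stone <- function(model, stones = 128, iters = 2000,
                           burnin_frac = 0.25, seed = 1L, alpha = 0.3,
                           verbose = FALSE) {
  stopifnot(inherits(model, "mcmc_model"))
  if (stones < 2) abort("Need at least 2 stones.")
  powers <- (seq(0, stones - 1) / (stones - 1))^(1 / alpha)
  burn <- max(1L, floor(iters * burnin_frac))
  init <- NULL
  logZ <- 0
  mean_ll <- numeric(stones)
  contrib <- rep(NA_real_, stones)
  for (s in seq_len(stones)) {
    fit <- run_mcmc(model, iterations = iters, burnin = burn, thin = 1L,
                    seed = seed + s, power = powers[s], init = init)
    init <- fit$final_state
    ll <- fit$draws$lnLikelihood
    mean_ll[s] <- mean(ll)
    if (s < stones) {
      db <- powers[s + 1L] - powers[s]
      w <- db * ll
      r <- log_mean_exp(w)
      if (!is.finite(r) || (sd(ll) == 0 && verbose)) {
        if (!is.finite(r)) {
          warn(sprintf("Degenerate stone %d (power %.4g); subdividing.", s, powers[s]))
          r <- subdivide_stone(model, powers[s], powers[s + 1L], iters, burn,
                               seed + 1000L * s, init, depth = 3L)
        }
      }
      contrib[s] <- r
      logZ <- logZ + r
    }
    if (verbose) {
      message(sprintf("stone %d / %d  power = %.5f  mean lnL = %.3f", s, stones, powers[s], mean_ll[s]))
    }
  }
  structure(
    list(
      log_marginal = logZ,
      stone_table = tibble(stone = seq_len(stones), power = powers,
                           mean_lnL = mean_ll, log_ratio = contrib),
      stones = stones, iters = iters, seed = seed
    ),
    class = "evidence_estimate"
  )
}

log_mean_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

subdivide_stone <- function(model, b_lo, b_hi, iters, burn, seed, init, depth) {
  mid <- (b_lo + b_hi) / 2
  ratio_from <- function(b_from, b_to, sd_) {
    fit <- run_mcmc(model, iterations = iters, burnin = burn, thin = 1L,
                    seed = sd_, power = b_from, init = init)
    log_mean_exp((b_to - b_from) * fit$draws$lnLikelihood)
  }
  r1 <- ratio_from(b_lo, mid, seed)
  r2 <- ratio_from(mid, b_hi, seed + 1L)
  if ((!is.finite(r1) || !is.finite(r2)) && depth > 0L) {
    r1 <- if (is.finite(r1)) r1 else subdivide_stone(model, b_lo, mid, iters, burn, seed + 2L, init, depth - 1L)
    r2 <- if (is.finite(r2)) r2 else subdivide_stone(model, mid, b_hi, iters, burn, seed + 3L, init, depth - 1L)
  }
  r1 + r2
}

#' @export
print.evidence_estimate <- function(x, ...) {
  cat(sprintf("<evidence_estimate> log marginal likelihood = %.4f (%d stones)\n",
              x$log_marginal, x$stones))
  invisible(x)
}
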