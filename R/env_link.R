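# Environmentally dependent diversification models.  All four link the
# epoch rates (present-to-past indexing, epoch 1 = present) to an
# environmental series through the correlation factor beta:
#
#   ln(rate_i) = ln(rate_{i-1}) + beta * deltaE_i  (+ stochastic variation)
#
# beta > 0: rates rise when the environmental variable rises; beta < 0:
# rates rise when it falls.  Only this exponential dependency is
# implemented: it keeps rates positive by construction, whereas a linear
# dependency can produce negative rates.  At beta = 0 each model collapses
# exactly to its environment-free counterpart in the rate priors.

check_delta <- function(delta_e, k) {
  if (length(delta_e) != k) {
    abort(sprintf("`delta_e` must have one entry per epoch (%d), got %d; the first entry (present epoch) is the anchor and must be 0.",
                  k, length(delta_e)))
  }
  delta_e
}

#' Deterministic environment-linked rate trajectory
#'
#' The `fixed` environmental model: rates follow the environmental
#' differences exactly, `ln(rate_i) = ln(rate_{i-1}) + beta * delta_e[i]`
#' with `rate_1 = lambda0` at the present.  Equivalent, by telescoping, to
#' `rate_i = lambda0 * exp(beta * (E_i - E_1))`, so the trajectory depends
#' only on environmental differences, never on the absolute level.
#'
#' @param lambda0 present-day rate (> 0).
#' @param beta correlation factor (any real).
#' @param delta_e per-epoch environmental first differences, present to
#'   past, as produced by [bin_environment()]/[env_deltas()]; the first
#'   entry is ignored (taken as 0).
#' @return Numeric vector of `length(delta_e)` positive rates.
#' @export
fixed_env_rates <- function(lambda0, beta, delta_e) {
  if (!is.finite(lambda0) || lambda0 <= 0) abort("`lambda0` must be > 0.")
  k <- length(delta_e)
  d <- c(0, delta_e[-1L])
  exp(log(lambda0) + beta * cumsum(d))
}

#' UCLN environmental log prior
#'
#' Uncorrelated lognormal variation around the deterministic
#' environment-linked trajectory: the deviations
#' `eps_i = ln(rate_i) - ln(rate_hat_i)`, with `rate_hat` from
#' [fixed_env_rates()], are iid `Normal(0, sigma)`.  At `beta = 0` this is
#' the UCLN prior centered at `ln(lambda0)`.
#'
#' @param log_rates epoch log rates, present to past.
#' @inheritParams fixed_env_rates
#' @param sigma deviation standard deviation (> 0).
#' @return The summed log density (`k` terms).
#' @export
ucln_env_log_prior <- function(log_rates, lambda0, beta, delta_e, sigma) {
  check_sigma(sigma)
  k <- length(log_rates)
  check_delta(delta_e, k)
  eps <- log_rates - log(fixed_env_rates(lambda0, beta, delta_e))
  sum(dnorm(eps, 0, sigma, log = TRUE))
}

#' GMRF environmental log prior
#'
#' Brownian motion with an environmental trend on the log rates:
#' `ln(rate_i) ~ Normal(ln(rate_{i-1}) + beta * delta_e[i], sigma)` for
#' `i >= 2`.  The present-day rate is anchored at `lambda0` by the model
#' (not scored here), mirroring [gmrf_log_prior()], to which this
#' collapses at `beta = 0`.
#'
#' @inheritParams ucln_env_log_prior
#' @return The summed log density (`k - 1` increment terms).
#' @export
gmrf_env_log_prior <- function(log_rates, lambda0, beta, delta_e, sigma) {
  check_sigma(sigma)
  k <- length(log_rates)
  check_delta(delta_e, k)
  if (k < 2L) return(0)
  sum(dnorm(diff(log_rates), mean = beta * delta_e[-1L], sd = sigma, log = TRUE))
}

#' HSMRF environmental log prior
#'
#' The horseshoe Markov random field with an environmental trend:
#' `gamma_i ~ halfCauchy(0, 1)` and
#' `ln(rate_i) ~ Normal(ln(rate_{i-1}) + beta * delta_e[i], sigma * gamma_i)`.
#' Collapses to [gmrf_env_log_prior()] plus the half-Cauchy terms when all
#' `gamma_i = 1`, and to [hsmrf_log_prior()] at `beta = 0`.
#'
#' @inheritParams gmrf_env_log_prior
#' @param gamma positive local scales, one per increment.
#' @return The summed log density.
#' @export
hsmrf_env_log_prior <- function(log_rates, lambda0, beta, delta_e, sigma, gamma) {
  check_sigma(sigma)
  k <- length(log_rates)
  check_delta(delta_e, k)
  if (length(gamma) != k - 1L) {
    abort(sprintf("`gamma` must have one local scale per increment (%d).", k - 1L))
  }
  if (any(gamma <= 0)) abort("All local scales `gamma` must be > 0.")
  if (k < 2L) return(0)
  sum(dhalfcauchy(gamma, scale = 1, log = TRUE)) +
    sum(dnorm(diff(log_rates), mean = beta * delta_e[-1L], sd = sigma * gamma, log = TRUE))
}

#' Default scale for the correlation-factor prior
#'
#' The prior on `beta` is `Normal(0, sd)`: symmetric and centered at zero,
#' so that the prior odds of a negative versus positive correlation are
#' exactly 1 (the construction the posterior-odds Bayes factor relies on).
#' The default scale is chosen so that `beta` times the observed range of
#' the environmental variable spans about +/- 3 log-rate units.
#'
#' @param env_values raw or binned environmental values.
#' @return A positive scalar prior standard deviation.
#' @export
default_beta_sd <- function(env_values) {
  r <- diff(range(env_values, na.rm = TRUE))
  if (r <= 0) return(1)
  3 / r
}
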