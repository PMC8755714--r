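# Log-prior densities for epoch-wise log-rate vectors (present-to-past
# indexing).  Three families: uncorrelated lognormal (UCLN), a first-order
# Gaussian Markov random field (GMRF, a discretized Brownian motion on the
# log rates), and a horseshoe Markov random field (HSMRF) whose
# per-increment local scales gamma_i allow abrupt rate jumps while
# shrinking toward locally constant trajectories.

#' Half-Cauchy log density
#'
#' @param x non-negative quantiles.
#' @param scale scale parameter (> 0).
#' @param log return the log density?
#' @return (Log) density values; `-Inf`/0 for `x < 0`.
#' @export
dhalfcauchy <- function(x, scale = 1, log = FALSE) {
  out <- log(2) + dcauchy(x, location = 0, scale = scale, log = TRUE)
  out[x < 0] <- -Inf
  if (log) out else exp(out)
}

check_sigma <- function(sigma) {
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  sigma
}

#' Uncorrelated lognormal (UCLN) log prior
#'
#' Independent and identically distributed log rates:
#' `ln(rate_i) ~ Normal(m0, sigma)` for every epoch.
#'
#' @param log_rates numeric vector of epoch log rates (present to past).
#' @param m0 prior mean of the log rates.
#' @param sigma prior standard deviation (> 0).
#' @return The summed log density.
#' @export
ucln_log_prior <- function(log_rates, m0, sigma) {
  check_sigma(sigma)
  sum(dnorm(log_rates, mean = m0, sd = sigma, log = TRUE))
}

#' Gaussian Markov random field (GMRF) log prior
#'
#' First-order autocorrelated log rates, a discretized Brownian motion:
#' `ln(rate_i) ~ Normal(ln(rate_{i-1}), sigma)` for `i >= 2`.  The
#' first-epoch rate carries its own base prior at the model level and is
#' not scored here.
#'
#' @inheritParams ucln_log_prior
#' @param sigma increment standard deviation (> 0).
#' @return The summed log density of the `k - 1` increments.
#' @export
gmrf_log_prior <- function(log_rates, sigma) {
  check_sigma(sigma)
  if (length(log_rates) < 2L) return(0)
  sum(dnorm(diff(log_rates), mean = 0, sd = sigma, log = TRUE))
}

#' Horseshoe Markov random field (HSMRF) log prior
#'
#' Like the GMRF but with a local scale per increment,
#' `gamma_i ~ halfCauchy(0, 1)` and
#' `ln(rate_i) ~ Normal(ln(rate_{i-1}), sigma * gamma_i)`, which permits
#' occasional large jumps while smoothing elsewhere.  The half-Cauchy
#' terms for `gamma` are included in the returned density.
#'
#' @inheritParams gmrf_log_prior
#' @param gamma positive local scales, one per increment (length
#'   `length(log_rates) - 1`).
#' @return The summed log density.
#' @export
hsmrf_log_prior <- function(log_rates, sigma, gamma) {
  check_sigma(sigma)
  k1 <- length(log_rates) - 1L
  if (length(gamma) != k1) {
    abort(sprintf("`gamma` must have one local scale per increment (%d), got %d.",
                  k1, length(gamma)))
  }
  if (any(!is.finite(gamma)) || any(gamma <= 0)) abort("All local scales `gamma` must be > 0.")
  if (k1 < 1L) return(0)
  sum(dhalfcauchy(gamma, scale = 1, log = TRUE)) +
    sum(dnorm(diff(log_rates), mean = 0, sd = sigma * gamma, log = TRUE))
}

#' Sample trajectories from the rate priors
#'
#' Generative counterparts of the log-prior densities, used for
#' self-consistency checks and prior-predictive simulation.
#'
#' @param k number of epochs.
#' @param m0,sigma UCLN location and scale.
#' @return Numeric vector of `k` log rates (present to past); for
#'   `sample_hsmrf()` a list with elements `log_rates` and `gamma`.
#' @export
sample_ucln <- function(k, m0, sigma) {
  rnorm(k, mean = m0, sd = check_sigma(sigma))
}

#' @rdname sample_ucln
#' @param log_rate0 first-epoch (present-day) log rate anchoring the
#'   random walk.
#' @export
sample_gmrf <- function(k, log_rate0, sigma) {
  check_sigma(sigma)
  cumsum(c(log_rate0, rnorm(k - 1L, 0, sigma)))
}

#' @rdname sample_ucln
#' @export
sample_hsmrf <- function(k, log_rate0, sigma) {
  check_sigma(sigma)
  gamma <- abs(rcauchy(k - 1L))
  list(
    log_rates = cumsum(c(log_rate0, rnorm(k - 1L, 0, sigma * gamma))),
    gamma = gamma
  )
}

#' Global-scale hyperprior calibration for MRF priors
#'
#' The increment scale `sigma` gets a half-Cauchy(0, zeta) hyperprior.
#' `zeta` is calibrated so that the marginal prior -- integrating `sigma`
#' over its half-Cauchy hyperprior (and, for the HSMRF, the local scales
#' over theirs) -- expects about ln(2) "effective shifts" (an adjacent
#' pair of epochs whose rates differ by more than a factor of 2) across
#' the `k - 1` increments.
#'
#' @param k number of epochs (>= 2).
#' @param model `"gmrf"` or `"hsmrf"`.
#' @return The half-Cauchy scale `zeta` (> 0).
#' @export
mrf_global_scale <- function(k, model = c("gmrf", "hsmrf")) {
  model <- match.arg(model)
  if (k < 2L) abort("Need at least 2 epochs to calibrate an MRF scale.")
  target <- log(2) / (k - 1L)
  if (target >= 1) return(1)
  shift_prob_sigma <- function(sigma) {
    if (model == "gmrf") {
      2 * pnorm(-log(2) / sigma)
    } else {
      vapply(sigma, function(s) {
        integrate(function(u) {
          g <- tan(pi * u / 2)   # gamma ~ halfCauchy(0,1)
          2 * pnorm(-log(2) / (s * g))
        }, 0, 1, rel.tol = 1e-8)$value
      }, numeric(1))
    }
  }
  marginal_shift_prob <- function(zeta) {
    integrate(function(u) {
      shift_prob_sigma(zeta * tan(pi * u / 2))   # sigma ~ halfCauchy(0,zeta)
    }, 0, 1, rel.tol = 1e-8)$value
  }
  uniroot(function(z) marginal_shift_prob(z) - target,
          lower = 1e-10, upper = 1e4, tol = 1e-12)$root
}
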