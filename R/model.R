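#' Build an episodic diversification model for MCMC
#'
#' Assembles the full Bayesian model -- episodic birth-death likelihood,
#' rate priors, optional environmental link, and taxon-sampling scheme --
#' as an [mcmc_model()] ready for [run_mcmc()] and [stepping_stone()].
#'
#' Epochs are equal-width age intervals indexed present to past (epoch 1
#' = present).  Speciation and extinction rates get independent,
#' identically structured priors with their own hyperparameters.  The
#' prior families are:
#'
#' * `"constant"`: a single rate per process (`lambda0`, `mu0`, each
#'   Uniform(0, 100) on the natural scale).
#' * `"ucln"`: iid lognormal epoch rates around a location `m0`
#'   (Uniform(-10, 5) on the log scale).
#' * `"gmrf"` / `"hsmrf"`: first-order Markov random fields on the log
#'   rates anchored at the present-day rate (`lambda0`, `mu0` ~
#'   Uniform(0, 100)); the HSMRF adds half-Cauchy local scales per
#'   increment.  The global increment scale `sigma` gets a half-Cauchy
#'   hyperprior calibrated by [mrf_global_scale()].
#'
#' Supplying `env` turns each family into its environmentally dependent
#' counterpart (the `"constant"` family becomes the `fixed` link model):
#' correlation factors `beta_lambda`, `beta_mu` with symmetric zero-mean
#' normal priors scale the per-epoch environmental differences into
#' log-rate changes.  At `beta = 0` every linked model collapses exactly
#' to its environment-free counterpart.
#'
#' MRF fields are parameterized non-centered (standard-normal increments
#' `eta` updated by elliptical slice sampling); scalars use adaptive
#' random-walk moves.
#'
#' @param tree a [time_tree][as_time_tree].
#' @param epochs number of equal-width age epochs.  The epoch counts
#'   explored in practice are 4, 10, 20, 50, 100, 200; other values are
#'   accepted with a warning.
#' @param prior `"constant"`, `"ucln"`, `"gmrf"`, or `"hsmrf"`.
#' @param env optional environmental series: either the binned tibble
#'   from [bin_environment()] (on the same epoch grid) or a raw
#'   `age_mya`/`value` tibble, which is binned internally.
#' @param sampling `"uniform"` (sampling fraction `rho` at the present)
#'   or `"empirical"` (clade-informed missing species; requires
#'   `clades`).
#' @param rho sampling fraction for uniform sampling.
#' @param clades clade table (see [read_clade_table()]) for empirical
#'   sampling; resolved against `tree` if not already.
#' @param clade_age `"crown"` or `"stem"` window for missing speciation
#'   times (see [empirical_sampling_log_density()]).
#' @param beta_prior_sd prior standard deviation of the correlation
#'   factors; default [default_beta_sd()] of the binned series.
#' @param sigma_scale half-Cauchy scale of the `sigma` hyperprior;
#'   default [mrf_global_scale()] for MRF families, 1 for UCLN.
#' @return An [mcmc_model()] whose `info` records the epoch table, the
#'   environmental deltas, and the configuration.
#' @export
div_model <- function(tree, epochs = 10,
                      prior = c("gmrf", "hsmrf", "ucln", "constant"),
                      env = NULL,
                      sampling = c("uniform", "empirical"),
                      rho = 1, clades = NULL,
                      clade_age = c("crown", "stem"),
                      beta_prior_sd = NULL, sigma_scale = NULL) {
  prior <- match.arg(prior)
  sampling <- match.arg(sampling)
  clade_age <- match.arg(clade_age)
  stopifnot(inherits(tree, "time_tree"))
  k <- as.integer(epochs)
  if (k < 1L) abort("`epochs` must be >= 1.")
  if (!k %in% c(1L, 4L, 10L, 20L, 50L, 100L, 200L)) {
    warn(sprintf("Epoch count %d is outside the usual set {4, 10, 20, 50, 100, 200}.", k))
  }
  td <- tree_lik_data(tree)
  boundaries <- seq(0, td$root_age, length.out = k + 1L)
  width <- td$root_age / k

  has_env <- !is.null(env)
  delta <- rep(0, k)
  env_binned <- NULL
  if (has_env) {
    if (all(c("age_mya", "value") %in% names(env))) {
      env_binned <- bin_environment(env, seq(0, td$root_age, by = width))
    } else if (all(c("epoch", "env_mean", "delta") %in% names(env))) {
      if (nrow(env) != k) {
        abort(sprintf("Binned environment has %d epochs but the model uses %d; bin on a shared grid.",
                      nrow(env), k))
      }
      env_binned <- env
    } else {
      abort("`env` must be a raw `age_mya`/`value` series or the output of `bin_environment()`.")
    }
    delta <- env_deltas(env_binned)
    if (is.null(beta_prior_sd)) beta_prior_sd <- default_beta_sd(env_binned$env_mean)
  }

  if (is.null(sigma_scale)) {
    sigma_scale <- if (prior %in% c("gmrf", "hsmrf") && k >= 2) {
      mrf_global_scale(k, prior)
    } else {
      1
    }
  }

  # empirical-sampling precomputation
  empirical <- sampling == "empirical"
  if (empirical) {
    if (is.null(clades)) abort("Empirical sampling requires a `clades` table.")
    cl <- validate_resolved_clades(clades, tree)
    age_col <- if (clade_age == "crown") cl$mrca_age else cl$stem_age
    if (any(age_col > td$root_age + 1e-9)) abort("Clade age exceeds the root age.")
    c_fwd <- td$root_age - age_col
    k_missing <- cl$missing
    m_total <- attr(cl, "m_total")
    rho <- 1
  }
  if (rho <= 0 || rho > 1) abort("`rho` must lie in (0, 1].")

  trend_cum <- function(beta) beta * cumsum(c(0, delta[-1L]))

  # parameter layout -------------------------------------------------------
  uses_anchor <- prior %in% c("constant", "gmrf", "hsmrf") || (prior == "ucln" && has_env)
  uses_m0 <- prior == "ucln" && !has_env
  uses_sigma <- prior != "constant"
  uses_eta <- prior != "constant"
  n_eta <- if (prior == "ucln") k else k - 1L
  uses_gamma <- prior == "hsmrf" && k >= 2L

  par_names <- character(0)
  add <- function(nm) par_names <<- c(par_names, nm)
  for (s in c("lambda", "mu")) {
    if (uses_anchor) add(paste0("log_", s, "0"))
    if (uses_m0) add(paste0("m0_", s))
    if (has_env) add(paste0("beta_", s))
    if (uses_sigma) add(paste0("log_sigma_", s))
    if (uses_eta && n_eta > 0) add(paste0("eta_", s, "_", seq_len(n_eta)))
    if (uses_gamma) add(paste0("log_gamma_", s, "_", seq_len(k - 1L)))
  }
  pidx <- function(pat) grep(pat, par_names)

  side_rates <- function(theta, s) {
    base <- if (uses_m0) {
      theta[[paste0("m0_", s)]]
    } else {
      theta[[paste0("log_", s, "0")]]
    }
    lr <- rep(base, k)
    if (has_env) lr <- lr + trend_cum(theta[[paste0("beta_", s)]])
    if (uses_eta && n_eta > 0) {
      eta <- theta[paste0("eta_", s, "_", seq_len(n_eta))]
      sig <- exp(theta[[paste0("log_sigma_", s)]])
      if (prior == "ucln") {
        lr <- lr + sig * eta
      } else if (prior == "gmrf") {
        lr <- lr + sig * c(0, cumsum(eta))
      } else if (prior == "hsmrf") {
        gam <- exp(theta[paste0("log_gamma_", s, "_", seq_len(k - 1L))])
        lr <- lr + c(0, cumsum(sig * gam * eta))
      }
    }
    unname(lr)
  }

  log_prior <- function(theta) {
    lp <- 0
    for (s in c("lambda", "mu")) {
      if (uses_anchor) {
        l0 <- theta[[paste0("log_", s, "0")]]
        if (l0 >= log(100)) return(-Inf)
        lp <- lp + l0 - log(100)           # Uniform(0, 100) on the natural scale
      }
      if (uses_m0) {
        m0 <- theta[[paste0("m0_", s)]]
        if (m0 < -10 || m0 > 5) return(-Inf)
        lp <- lp - log(15)
      }
      if (has_env) {
        lp <- lp + dnorm(theta[[paste0("beta_", s)]], 0, beta_prior_sd, log = TRUE)
      }
      if (uses_sigma) {
        ls <- theta[[paste0("log_sigma_", s)]]
        lp <- lp + dhalfcauchy(exp(ls), scale = sigma_scale, log = TRUE) + ls
      }
      if (uses_eta && n_eta > 0) {
        lp <- lp + sum(dnorm(theta[paste0("eta_", s, "_", seq_len(n_eta))], log = TRUE))
      }
      if (uses_gamma) {
        lg <- theta[paste0("log_gamma_", s, "_", seq_len(k - 1L))]
        lp <- lp + sum(dhalfcauchy(exp(lg), scale = 1, log = TRUE) + lg)
      }
    }
    lp
  }

  log_lik <- function(theta) {
    log_lambda <- side_rates(theta, "lambda")    # present to past
    log_mu <- side_rates(theta, "mu")
    # numerical support: beyond |log rate| = 20 the log-space sums lose
    # additive precision; rates that large are unphysical anyway
    if (any(abs(log_lambda) > 20) || any(abs(log_mu) > 20)) return(-Inf)
    lambda <- exp(log_lambda)
    mu <- exp(log_mu)
    cst <- bd_constants(boundaries, rev(lambda), rev(mu), rho)
    ll <- bd_tree_log_density(td, cst)
    if (empirical) {
      ll <- ll + bd_missing_clade_terms(cst, c_fwd, k_missing, m_total, td$n)
    }
    ll
  }

  derived <- function(theta) {
    lam <- exp(side_rates(theta, "lambda"))
    mu <- exp(side_rates(theta, "mu"))
    setNames(c(lam, mu), c(paste0("lambda_", seq_len(k)), paste0("mu_", seq_len(k))))
  }

  par_init <- function() {
    lam_hat <- max(log(max(td$n, 3) / 2) / td$root_age, 1e-3)
    theta <- numeric(length(par_names))
    names(theta) <- par_names
    for (s in c("lambda", "mu")) {
      start <- log(lam_hat) + if (s == "mu") log(0.5) else 0
      if (uses_anchor) theta[[paste0("log_", s, "0")]] <- start + rnorm(1, 0, 0.2)
      if (uses_m0) theta[[paste0("m0_", s)]] <- start + rnorm(1, 0, 0.2)
      if (has_env) theta[[paste0("beta_", s)]] <- rnorm(1, 0, 0.1 * beta_prior_sd)
      if (uses_sigma) theta[[paste0("log_sigma_", s)]] <- log(0.1) + rnorm(1, 0, 0.2)
      if (uses_eta && n_eta > 0) {
        theta[paste0("eta_", s, "_", seq_len(n_eta))] <- rnorm(n_eta, 0, 0.1)
      }
      if (uses_gamma) {
        theta[paste0("log_gamma_", s, "_", seq_len(k - 1L))] <- rnorm(k - 1L, 0, 0.1)
      }
    }
    theta
  }

  blocks <- list()
  add_block <- function(name, pars, type, scale = 0.3) {
    blocks[[length(blocks) + 1L]] <<- list(name = name, pars = pars, type = type, scale = scale)
  }
  for (s in c("lambda", "mu")) {
    if (uses_anchor) add_block(paste0("log_", s, "0"), paste0("log_", s, "0"), "rw", 0.3)
    if (uses_m0) add_block(paste0("m0_", s), paste0("m0_", s), "rw", 0.3)
    if (has_env) add_block(paste0("beta_", s), paste0("beta_", s), "rw", 0.3 * beta_prior_sd)
    if (uses_sigma) add_block(paste0("log_sigma_", s), paste0("log_sigma_", s), "rw", 0.5)
    if (uses_eta && n_eta > 0) {
      add_block(paste0("eta_", s), paste0("eta_", s, "_", seq_len(n_eta)), "ess")
    }
    if (uses_gamma) {
      add_block(paste0("log_gamma_", s), paste0("log_gamma_", s, "_", seq_len(k - 1L)), "rw", 0.4)
    }
  }

  mcmc_model(
    par_init = par_init,
    log_prior = log_prior,
    log_lik = log_lik,
    blocks = blocks,
    derived = derived,
    info = list(
      kind = "episodic_bd",
      prior = prior, epochs = k, has_env = has_env,
      sampling = sampling, rho = rho, clade_age = clade_age,
      root_age = td$root_age, n_tips = td$n,
      boundaries = boundaries, delta = delta,
      env_binned = env_binned,
      beta_prior_sd = if (has_env) beta_prior_sd else NA_real_,
      sigma_scale = sigma_scale,
      epoch_table = tibble(
        epoch = seq_len(k),
        age_young = (seq_len(k) - 1) * width,
        age_old = seq_len(k) * width,
        age_mid = (seq_len(k) - 0.5) * width
      )
    )
  )
}
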