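# Generic adaptive MCMC engine.
#
# A model is a plain list (class "mcmc_model") with
#   $par_init()        : named numeric parameter vector (fresh draw)
#   $log_prior(theta)  : scalar log prior
#   $log_lik(theta)    : scalar log likelihood
#   $blocks            : list of blocks, each
#                          list(name, pars, type = "rw" | "ess", scale)
#                        "rw"  - joint Gaussian random-walk Metropolis with
#                                Robbins-Monro scale adaptation (target
#                                acceptance 0.35), frozen after burn-in;
#                        "ess" - elliptical slice sampling; the block's
#                                coordinates must carry iid Normal(0, 1)
#                                priors (non-centered fields).
#   $derived(theta)    : optional named vector of derived quantities to
#                        record alongside the raw parameters
#
# The diversification models in div_model() are built on this contract; a
# hand-built toy model (e.g. a conjugate normal) plugs into the same
# engine, which is how the engine is validated against closed forms.

#' Construct an MCMC model object
#'
#' Low-level constructor for the model contract consumed by
#' [run_mcmc()] and [stepping_stone()]; see [div_model()] for the
#' diversification models built on top of it.
#'
#' @param par_init function returning a named numeric start vector.
#' @param log_prior,log_lik functions of the parameter vector returning a
#'   scalar.
#' @param blocks list of update blocks (`name`, `pars`, `type`, `scale`).
#' @param derived optional function of the parameter vector returning a
#'   named vector of derived quantities recorded in the trace.
#' @param info optional list of metadata carried along.
#' @return An object of class `mcmc_model`.
#' @export
mcmc_model <- function(par_init, log_prior, log_lik, blocks, derived = NULL,
                       info = list()) {
  structure(
    list(par_init = par_init, log_prior = log_prior, log_lik = log_lik,
         blocks = blocks, derived = derived, info = info),
    class = "mcmc_model"
  )
}

ess_update <- function(theta, idx, log_target, cur_target) {
  # elliptical slice sampling on iid N(0,1) coordinates `idx`
  nu <- rnorm(length(idx))
  logy <- cur_target + log(runif(1))
  angle <- runif(1, 0, 2 * pi)
  lo <- angle - 2 * pi
  hi <- angle
  eta0 <- theta[idx]
  repeat {
    prop <- theta
    prop[idx] <- eta0 * cos(angle) + nu * sin(angle)
    lt <- log_target(prop)
    if (is.finite(lt) && lt > logy) {
      return(list(theta = prop, target = lt))
    }
    if (angle < 0) hi <- angle else lo <- angle
    angle <- runif(1, lo, hi)
    if (hi - lo < 1e-12) {
      return(list(theta = theta, target = cur_target))
    }
  }
}

#' Run adaptive MCMC
#'
#' Metropolis-within-Gibbs over the model's update blocks: adaptive
#' random-walk moves on scalar/low-dimensional blocks and elliptical slice
#' sampling on non-centered Gaussian field blocks.  Proposal scales adapt
#' during burn-in only and are frozen afterwards, so the retained chain is
#' a valid MCMC sample.
#'
#' @param model an [mcmc_model()] (for example from [div_model()]).
#' @param iterations total number of sweeps.
#' @param burnin number of initial sweeps discarded (default 10%).
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer RNG seed (mandatory, for reproducibility).
#' @param power likelihood tempering exponent in `[0, 1]` (used by
#'   [stepping_stone()]; 1 = the posterior).
#' @param init optional named start vector overriding `model$par_init()`.
#' @param verbose print progress to stderr every 1000 sweeps?
#' @return An object of class `epochdiv_fit` with elements `draws` (a
#'   tibble: `iteration`, `lnPosterior`, `lnLikelihood`, `lnPrior`, then
#'   parameters and derived quantities), `acceptance`, `settings`, and
#'   `model`.
#' @export
run_mcmc <- function(model, iterations = 5000, burnin = max(1L, floor(iterations / 10)),
                     thin = 1L, seed = 1L, power = 1, init = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(model, "mcmc_model"))
  if (is.null(seed)) abort("`seed` is mandatory.")
  set.seed(seed)
  lp_full <- function(theta) {
    pr <- model$log_prior(theta)
    if (!is.finite(pr)) return(list(prior = pr, lik = NA_real_, post = -Inf))
    ll <- model$log_lik(theta)
    list(prior = pr, lik = ll, post = pr + power * ll)
  }

  theta <- if (!is.null(init)) init else model$par_init()
  state <- lp_full(theta)
  tries <- 0
  while (!is.finite(state$post) && tries < 100) {
    theta <- model$par_init()
    state <- lp_full(theta)
    tries <- tries + 1
  }
  if (!is.finite(state$post)) {
    abort("Could not find a starting point with finite posterior after 100 prior draws.")
  }

  blocks <- model$blocks
  nb <- length(blocks)
  scales <- vapply(blocks, function(b) b$scale %||% 0.5, numeric(1))
  acc_n <- integer(nb)
  try_n <- integer(nb)
  par_names <- names(theta)
  eta_lp <- function(th, pars) sum(dnorm(th[pars], log = TRUE))

  n_keep <- max(0L, (iterations - burnin) %/% thin)
  first_derived <- if (!is.null(model$derived)) model$derived(theta) else NULL
  ncol_out <- length(theta) + length(first_derived)
  out <- matrix(NA_real_, nrow = n_keep, ncol = ncol_out)
  colnames(out) <- c(par_names, names(first_derived))
  meta <- matrix(NA_real_, nrow = n_keep, ncol = 4L,
                 dimnames = list(NULL, c("iteration", "lnPosterior", "lnLikelihood", "lnPrior")))
  kept <- 0L

  for (it in seq_len(iterations)) {
    for (bi in seq_len(nb)) {
      b <- blocks[[bi]]
      idx <- b$pars
      if (b$type == "rw") {
        prop <- theta
        prop[idx] <- prop[idx] + rnorm(length(idx), 0, scales[bi])
        cand <- lp_full(prop)
        try_n[bi] <- try_n[bi] + 1L
        accept <- is.finite(cand$post) &&
          log(runif(1)) < (cand$post - state$post)
        if (accept) {
          theta <- prop
          state <- cand
          acc_n[bi] <- acc_n[bi] + 1L
        }
        if (it <= burnin) {
          rate <- if (accept) 1 else 0
          scales[bi] <- exp(log(scales[bi]) + (rate - 0.35) / sqrt(1 + try_n[bi] / nb))
        }
      } else if (b$type == "ess") {
        # target excludes the iid N(0,1) prior on the block coordinates
        last_state <- NULL
        tgt <- function(th) {
          s <- lp_full(th)
          last_state <<- s
          if (!is.finite(s$post)) return(-Inf)
          s$post - eta_lp(th, idx)
        }
        res <- ess_update(theta, idx, tgt, state$post - eta_lp(theta, idx))
        if (!identical(res$theta, theta)) {
          theta <- res$theta
          state <- last_state
        }
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      vals <- theta
      if (!is.null(model$derived)) vals <- c(vals, model$derived(theta))
      out[kept, ] <- vals
      meta[kept, ] <- c(it, state$post, state$lik, state$prior)
    }
    if (verbose && it %% 1000L == 0L) {
      message(sprintf("iteration %d / %d  lnPosterior = %.3f", it, iterations, state$post))
    }
  }

  draws <- as_tibble(cbind(as.data.frame(meta), as.data.frame(out[seq_len(kept), , drop = FALSE])))
  acceptance <- tibble(
    block = vapply(blocks, `[[`, character(1), "name"),
    type = vapply(blocks, `[[`, character(1), "type"),
    proposed = try_n,
    accepted = acc_n,
    rate = ifelse(try_n > 0, acc_n / pmax(try_n, 1L), NA_real_),
    scale = scales
  )
  structure(
    list(draws = draws, acceptance = acceptance,
         settings = list(iterations = iterations, burnin = burnin,
                         thin = thin, seed = seed, power = power),
         final_state = theta, model = model),
    class = "epochdiv_fit"
  )
}

#' @export
print.epochdiv_fit <- function(x, ...) {
  cat(sprintf(
    "<epochdiv_fit> %d retained samples (%d iterations, burn-in %d, seed %d)\n",
    nrow(x$draws), x$settings$iterations, x$settings$burnin, x$settings$seed
  ))
  invisible(x)
}

#' Effective sample size via the autocorrelation time
#'
#' `n / (1 + 2 * sum(acf))`, truncating the autocorrelation sum at the
#' first non-positive pairwise sum (initial positive sequence).
#'
#' @param x numeric sample vector.
#' @return Estimated effective sample size.
#' @export
ess_autocorr <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = min(n - 1L, 10L * floor(sqrt(n))), plot = FALSE)$acf[-1]
  tau <- 1
  i <- 1L
  while (i < length(rho)) {
    pair <- rho[i] + rho[i + 1L]
    if (!is.finite(pair) || pair <= 0) break
    tau <- tau + 2 * pair
    i <- i + 2L
  }
  max(1, n / tau)
}
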