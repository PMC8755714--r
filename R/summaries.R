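#' Posterior rate-through-time summary
#'
#' Per-epoch posterior medians and central 95% intervals for the
#' speciation rate, extinction rate, and net diversification rate,
#' computed from the derived `lambda_i` / `mu_i` columns of a fitted
#' model's trace.
#'
#' @param fit an `epochdiv_fit` from [run_mcmc()] on a [div_model()].
#' @param prob width of the central credible interval.
#' @return A tibble with one row per epoch (present to past) and columns
#'   `epoch`, `age_mid`, `lambda_med`, `lambda_lo`, `lambda_hi`,
#'   `mu_med`, `mu_lo`, `mu_hi`, `netdiv_med`, `netdiv_lo`, `netdiv_hi`.
#' @export
summarize_rates <- function(fit, prob = 0.95) {
  stopifnot(inherits(fit, "epochdiv_fit"))
  info <- fit$model$info
  if (is.null(info$epochs)) abort("Fit does not carry an epoch structure.")
  k <- info$epochs
  draws <- fit$draws
  lam_cols <- paste0("lambda_", seq_len(k))
  mu_cols <- paste0("mu_", seq_len(k))
  if (!all(c(lam_cols, mu_cols) %in% names(draws))) {
    abort("Trace lacks per-epoch rate columns.")
  }
  a <- (1 - prob) / 2
  qs <- function(m) unname(apply(m, 2, quantile, probs = c(a, 0.5, 1 - a), names = FALSE))
  lam <- qs(as.matrix(draws[lam_cols]))
  mu <- qs(as.matrix(draws[mu_cols]))
  nd <- qs(as.matrix(draws[lam_cols]) - as.matrix(draws[mu_cols]))
  tibble(
    epoch = seq_len(k),
    age_mid = info$epoch_table$age_mid,
    lambda_med = lam[2, ], lambda_lo = lam[1, ], lambda_hi = lam[3, ],
    mu_med = mu[2, ], mu_lo = mu[1, ], mu_hi = mu[3, ],
    netdiv_med = nd[2, ], netdiv_lo = nd[1, ], netdiv_hi = nd[3, ]
  )
}

#' Tidy a fitted diversification model
#'
#' One row per sampled parameter (and derived per-epoch rate) with the
#' posterior median, central 95% interval, and effective sample size.
#'
#' @param x an `epochdiv_fit`.
#' @param ... unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`, `ess`.
#' @method tidy epochdiv_fit
#' @export
tidy.epochdiv_fit <- function(x, ...) {
  skip <- c("iteration", "lnPosterior", "lnLikelihood", "lnPrior")
  cols <- setdiff(names(x$draws), skip)
  purrr::map_dfr(cols, function(cn) {
    v <- x$draws[[cn]]
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    tibble(term = cn, estimate = q[2], conf.low = q[1], conf.high = q[3],
           ess = ess_autocorr(v))
  })
}

#' One-row fit summary
#'
#' @param x an `epochdiv_fit`.
#' @param ... unused.
#' @return A tibble with columns `iterations`, `burnin`, `retained`,
#'   `seed`, `max_lnLik`, `mean_accept`, `min_ess`.
#' @method glance epochdiv_fit
#' @export
glance.epochdiv_fit <- function(x, ...) {
  skip <- c("iteration", "lnPosterior", "lnLikelihood", "lnPrior")
  cols <- setdiff(names(x$draws), skip)
  ess <- vapply(cols, function(cn) ess_autocorr(x$draws[[cn]]), numeric(1))
  rw <- x$acceptance$type == "rw"
  tibble(
    iterations = x$settings$iterations,
    burnin = x$settings$burnin,
    retained = nrow(x$draws),
    seed = x$settings$seed,
    max_lnLik = max(x$draws$lnLikelihood),
    mean_accept = mean(x$acceptance$rate[rw], na.rm = TRUE),
    min_ess = if (length(ess)) min(ess) else NA_real_
  )
}

#' Write / read a posterior trace
#'
#' Tab-separated, one row per retained sample, full-precision floats so a
#' round trip reproduces the trace exactly.  Columns are `iteration`,
#' `lnPosterior`, `lnLikelihood`, `lnPrior`, then all named parameters
#' (including `beta_lambda` / `beta_mu` for environmental runs).
#'
#' @param trace an `epochdiv_fit` or its draws tibble.
#' @param path output TSV path.
#' @return `path` invisibly; `read_trace()` returns a tibble.
#' @export
write_trace <- function(trace, path) {
  draws <- if (inherits(trace, "epochdiv_fit")) trace$draws else as_tibble(trace)
  out <- draws
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(sprintf("Trace file not found: '%s'", path))
  readr::read_tsv(path, show_col_types = FALSE)
}
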