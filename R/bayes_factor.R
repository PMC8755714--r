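#' Posterior-odds Bayes factor for the sign of the correlation factor
#'
#' Under a prior for `beta` that is symmetric and centered at zero the
#' prior odds of `P(beta < 0) / P(beta > 0)` are exactly 1, so the Bayes
#' factor in favor of a negative correlation is simply the posterior odds
#' -- the fraction of MCMC samples with `beta < 0` over the fraction with
#' `beta > 0`.  The default add-one smoothing `(N_neg + 1) / (N_pos + 1)`
#' keeps the Bayes factor finite when every retained sample falls on one
#' side, in which case its value is bounded by the sample size (a trace
#' of 37500 all-negative samples gives 37501).
#'
#' @param fit an `epochdiv_fit` (or a draws tibble / numeric vector of
#'   beta samples).
#' @param parameter which correlation factor to test (default
#'   `"beta_lambda"`, the speciation-rate factor).
#' @param direction `"negative"` for BF(beta < 0) or `"positive"`.
#' @param smoothing `"add-one"` (default) or `"raw"` posterior odds.
#' @return A tibble with columns `parameter`, `direction`, `n_neg`,
#'   `n_pos`, `posterior_prob`, `bayes_factor`.
#' @export
bayes_factor_beta <- function(fit, parameter = "beta_lambda",
                              direction = c("negative", "positive"),
                              smoothing = c("add-one", "raw")) {
  direction <- match.arg(direction)
  smoothing <- match.arg(smoothing)
  beta <- if (is.numeric(fit)) {
    fit
  } else {
    draws <- if (inherits(fit, "epochdiv_fit")) fit$draws else fit
    if (!parameter %in% names(draws)) {
      abort(sprintf("No `%s` column in the trace; was this an environmental run?", parameter))
    }
    draws[[parameter]]
  }
  if (length(beta) == 0) abort("Empty trace.")
  n_neg <- sum(beta < 0)
  n_pos <- sum(beta > 0)
  num <- if (direction == "negative") n_neg else n_pos
  den <- if (direction == "negative") n_pos else n_neg
  bf <- if (smoothing == "add-one") (num + 1) / (den + 1) else num / den
  tibble(
    parameter = if (is.numeric(fit)) "beta" else parameter,
    direction = direction,
    n_neg = n_neg, n_pos = n_pos,
    posterior_prob = num / length(beta),
    bayes_factor = bf
  )
}

#' Label a Bayes factor on the conventional evidence scale
#'
#' @param bf Bayes factor(s).
#' @param thresholds ascending break points between categories.
#' @return Character vector of labels.
#' @export
bf_label <- function(bf, thresholds = c(1, 3.2, 10, 100)) {
  labels <- c("against", "barely worth mentioning", "substantial", "strong", "decisive")
  labels[findInterval(bf, thresholds) + 1L]
}
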