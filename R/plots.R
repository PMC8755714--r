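#' Plot posterior rates through time
#'
#' Posterior median and credible ribbon for the speciation and extinction
#' rates against age (x axis reversed: past on the left).
#'
#' @param rate_summary output of [summarize_rates()].
#' @return A ggplot object.
#' @export
plot_rates_through_time <- function(rate_summary) {
  long <- dplyr::bind_rows(
    dplyr::transmute(rate_summary, age = .data$age_mid, rate = "speciation",
                     med = .data$lambda_med, lo = .data$lambda_lo, hi = .data$lambda_hi),
    dplyr::transmute(rate_summary, age = .data$age_mid, rate = "extinction",
                     med = .data$mu_med, lo = .data$mu_lo, hi = .data$mu_hi)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$med,
                                     ymin = .data$lo, ymax = .data$hi,
                                     colour = .data$rate, fill = .data$rate)) +
    ggplot2::geom_ribbon(alpha = 0.25, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Myr before present)", y = "Rate (events / lineage / Myr)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_rates_through_time autoplot method for fitted models.
#' @param object an `epochdiv_fit`.
#' @param ... passed to [summarize_rates()].
#' @method autoplot epochdiv_fit
#' @export
autoplot.epochdiv_fit <- function(object, ...) {
  plot_rates_through_time(summarize_rates(object, ...))
}

#' Plot an environmental series and its epoch means
#'
#' @param env raw series (`age_mya`, `value`).
#' @param binned optional output of [bin_environment()] overlaid as
#'   epoch-wise steps.
#' @return A ggplot object.
#' @export
plot_env_series <- function(env, binned = NULL) {
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$age_mya, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (Myr before present)", y = "Environmental value") +
    ggplot2::theme_minimal()
  if (!is.null(binned)) {
    p <- p + ggplot2::geom_segment(
      data = binned,
      ggplot2::aes(x = .data$age_old, xend = .data$age_young,
                   y = .data$env_mean, yend = .data$env_mean),
      colour = "firebrick", linewidth = 0.8, inherit.aes = FALSE
    )
  }
  p
}

#' Posterior of the correlation factor
#'
#' Histogram of the posterior samples of a correlation factor with the
#' zero line marked; mass left of the line supports a negative
#' rate-environment correlation.
#'
#' @param fit an `epochdiv_fit` from an environmental run.
#' @param parameter `"beta_lambda"` (default) or `"beta_mu"`.
#' @return A ggplot object.
#' @export
plot_beta_posterior <- function(fit, parameter = "beta_lambda") {
  stopifnot(inherits(fit, "epochdiv_fit"))
  if (!parameter %in% names(fit$draws)) abort(sprintf("No `%s` in the trace.", parameter))
  df <- tibble(beta = fit$draws[[parameter]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$beta)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = parameter, y = "Posterior samples") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
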