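#' Read an environmental time series
#'
#' @param path CSV with columns `age_mya` (Myr before present) and
#'   `value` (for example ppm CO2 or degrees C).
#' @return A tibble with columns `age_mya`, `value`, sorted youngest
#'   first.
#' @export
read_env_series <- function(path) {
  if (!file.exists(path)) abort(sprintf("Environmental series not found: '%s'", path))
  env <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("age_mya", "value") %in% names(env))) {
    abort("Environmental series must have columns `age_mya` and `value`.")
  }
  validate_env_series(env[c("age_mya", "value")])
}

validate_env_series <- function(env) {
  env <- as_tibble(env)
  if (anyDuplicated(env$age_mya)) abort("Environmental series ages must be unique.")
  if (any(env$age_mya < 0)) abort("Environmental series ages must be >= 0.")
  dplyr::arrange(env, .data$age_mya)
}

#' Bin an environmental series onto an epoch grid
#'
#' Computes the arithmetic mean of the raw observations falling in each
#' epoch's age interval, together with first differences between adjacent
#' epochs.  Epochs are indexed present to past (epoch 1 = present-day
#' epoch) and an epoch's age interval is half-open so that an observation
#' exactly on a boundary belongs to the younger epoch.  Observations older
#' than the grid span are dropped (the series is truncated at the root
#' age).  Epochs without any observation are filled by linear
#' interpolation of neighboring epoch means, with a warning.
#'
#' @param env a tibble with columns `age_mya` and `value` (see
#'   [read_env_series()]).
#' @param grid an [epoch_grid()], or a numeric vector of age boundaries
#'   (ascending, starting at 0).
#' @return A tibble, one row per epoch ordered present to past, with
#'   columns `epoch`, `age_young`, `age_old`, `env_mean`, `n_obs`,
#'   `interpolated`, and `delta` (`delta[i] = env_mean[i] -
#'   env_mean[i-1]`, `delta[1] = 0`).
#' @export
bin_environment <- function(env, grid) {
  env <- validate_env_series(env)
  if (inherits(grid, "epoch_grid")) {
    T_ <- grid$boundaries[grid$k + 1L]
    breaks_age <- rev(T_ - grid$boundaries)
  } else {
    breaks_age <- as.numeric(grid)
    if (any(diff(breaks_age) <= 0) || breaks_age[1] != 0) {
      abort("Age boundaries must be ascending and start at 0.")
    }
  }
  k <- length(breaks_age) - 1L
  idx <- findInterval(env$age_mya, breaks_age, left.open = TRUE)
  idx[env$age_mya == 0] <- 1L
  keep <- idx >= 1L & idx <= k
  idx <- idx[keep]
  val <- env$value[keep]
  n_obs <- tabulate(idx, nbins = k)
  sums <- rep(0, k)
  agg <- tapply(val, idx, sum)
  sums[as.integer(names(agg))] <- agg
  env_mean <- ifelse(n_obs > 0, sums / pmax(n_obs, 1L), NA_real_)
  interpolated <- n_obs == 0L
  if (any(interpolated)) {
    if (all(interpolated)) {
      abort("No environmental observations fall within the grid span.")
    }
    warn(sprintf(
      "%d epoch(s) contain no environmental observations; filling by linear interpolation of neighboring epoch means.",
      sum(interpolated)
    ))
    filled <- approx(
      x = which(!interpolated), y = env_mean[!interpolated],
      xout = seq_len(k), rule = 2
    )$y
    env_mean[interpolated] <- filled[interpolated]
  }
  tibble(
    epoch = seq_len(k),
    age_young = breaks_age[-(k + 1L)],
    age_old = breaks_age[-1L],
    env_mean = env_mean,
    n_obs = n_obs,
    interpolated = interpolated,
    delta = c(0, diff(env_mean))
  )
}

#' Per-epoch environmental differences
#'
#' Extracts the first-difference vector `delta` (present to past, first
#' element 0) that the environmental link models consume.
#'
#' @param binned output of [bin_environment()].
#' @return Numeric vector of length `k`.
#' @export
env_deltas <- function(binned) {
  stopifnot(all(c("epoch", "delta") %in% names(binned)))
  binned$delta[order(binned$epoch)]
}

#' Synthetic Cenozoic-like CO2 curve
#'
#' A deterministic, smooth stand-in for a Cenozoic atmospheric CO2
#' record: Eocene highs around 1100 ppm (proxy compilations place the
#' early Eocene at roughly 1000-1500 ppm), a steep Oligocene-like
#' logistic decline centered near 31 Ma, near-modern values (~300 ppm)
#' through the Neogene, and a mild long-period oscillation.  It is
#' synthetic and exists so that simulations and tests require no external
#' data download.
#'
#' @param max_age oldest age in Myr.
#' @param by sampling step in Myr.
#' @return A tibble with columns `age_mya`, `value` (ppm).
#' @export
synthetic_cenozoic_co2 <- function(max_age = 60, by = 0.25) {
  age <- seq(0, max_age, by = by)
  value <- 300 + 810 / (1 + exp(-(age - 31) / 2.5)) + 30 * sin(age / 5.5)
  tibble(age_mya = age, value = value)
}
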