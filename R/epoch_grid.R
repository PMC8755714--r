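#' Epoch grids of piecewise-constant diversification rates
#'
#' An `epoch_grid` holds the episodic birth-death rate function: ordered
#' epoch boundaries in forward time (0 at the root, `T` at the present),
#' one speciation rate and one extinction rate per epoch, and the uniform
#' taxon-sampling fraction `rho` applied at the present.
#'
#' Epoch `j` covers forward time `[boundaries[j], boundaries[j + 1])`.
#'
#' @param boundaries strictly increasing numeric vector of length
#'   `k + 1`, starting at the root time (usually 0) and ending at the
#'   present `T`.
#' @param lambda,mu numeric vectors of length `k`; `lambda > 0`,
#'   `mu >= 0`.
#' @param rho sampling fraction at the present, in (0, 1].
#' @return An object of class `epoch_grid`.
#' @export
epoch_grid <- function(boundaries, lambda, mu, rho = 1) {
  boundaries <- as.numeric(boundaries)
  lambda <- as.numeric(lambda)
  mu <- as.numeric(mu)
  k <- length(boundaries) - 1L
  if (k < 1L) abort("Need at least two boundaries (one epoch).")
  if (any(diff(boundaries) <= 0)) abort("Epoch boundaries must be strictly increasing.")
  if (length(lambda) == 1L) lambda <- rep(lambda, k)
  if (length(mu) == 1L) mu <- rep(mu, k)
  if (length(lambda) != k || length(mu) != k) {
    abort(sprintf("Expected %d per-epoch rates, got %d lambda and %d mu.",
                  k, length(lambda), length(mu)))
  }
  if (any(!is.finite(lambda)) || any(lambda <= 0)) abort("All speciation rates must be finite and > 0.")
  if (any(!is.finite(mu)) || any(mu < 0)) abort("All extinction rates must be finite and >= 0.")
  if (!is.finite(rho) || rho <= 0 || rho > 1) abort("`rho` must lie in (0, 1].")
  structure(
    list(boundaries = boundaries, lambda = lambda, mu = mu, rho = rho, k = k),
    class = "epoch_grid"
  )
}

#' Build an epoch grid from equal-width age intervals
#'
#' The applied convention divides the tree span into `k` equal-width
#' intervals of age (epoch 1 at the present); this helper converts that
#' age-indexed description into the forward-time `epoch_grid` the
#' likelihood consumes. `lambda` and `mu` are given present-to-past
#' (element 1 = present-day epoch), matching the indexing of the rate
#' priors and environmental models.
#'
#' @param root_age tree span in Myr.
#' @param k number of epochs.
#' @param lambda,mu per-epoch rates ordered present to past (recycled if
#'   scalar).
#' @param rho sampling fraction at the present.
#' @return An `epoch_grid` (rates re-ordered onto the forward axis).
#' @export
epoch_grid_ages <- function(root_age, k, lambda, mu, rho = 1) {
  if (length(lambda) == 1L) lambda <- rep(lambda, k)
  if (length(mu) == 1L) mu <- rep(mu, k)
  stopifnot(length(lambda) == k, length(mu) == k)
  epoch_grid(
    boundaries = seq(0, root_age, length.out = k + 1L),
    lambda = rev(lambda),
    mu = rev(mu),
    rho = rho
  )
}

#' Age intervals of an epoch grid
#'
#' Returns the grid's epochs as a tibble ordered present to past, the
#' ordering used by the rate priors and environmental link models.
#'
#' @param grid an `epoch_grid`.
#' @return A tibble with columns `epoch` (1 = present), `age_young`,
#'   `age_old`, `age_mid`, `lambda`, `mu`.
#' @export
epoch_table <- function(grid) {
  stopifnot(inherits(grid, "epoch_grid"))
  T_ <- grid$boundaries[grid$k + 1L]
  age_old <- rev(T_ - grid$boundaries[-(grid$k + 1L)])
  age_young <- rev(T_ - grid$boundaries[-1L])
  tibble(
    epoch = seq_len(grid$k),
    age_young = age_young,
    age_old = age_old,
    age_mid = (age_young + age_old) / 2,
    lambda = rev(grid$lambda),
    mu = rev(grid$mu)
  )
}

#' @export
print.epoch_grid <- function(x, ...) {
  cat(sprintf(
    "<epoch_grid> %d epochs on [%.4g, %.4g] (forward time), rho = %.3g\n",
    x$k, x$boundaries[1], x$boundaries[x$k + 1L], x$rho
  ))
  invisible(x)
}
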