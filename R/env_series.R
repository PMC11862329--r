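#' Generate a stationary AR(1) timeseries
#'
#' First-order autoregression `X[t+1] = phi * X[t] + eps[t+1]` with standard
#' normal white noise. The first value is drawn from the stationary
#' distribution `N(0, 1/(1 - phi^2))` so the raw series carries no start-up
#' transient.
#'
#' @param phi Autocorrelation coefficient, `|phi| < 1`.
#' @param T Series length (at least 2).
#' @param seed Integer seed; identical inputs reproduce the series exactly.
#' @return Numeric vector of length `T`.
#' @export
generate_ar1 <- function(phi, T, seed) {
  T <- as.integer(T)
  if (T < 2L) stop("generate_ar1: T must be >= 2")
  eps <- with_seed(seed, rnorm(T))
  ar1_from_noise(phi, eps)
}

# AR(1) recursion from a given white-noise vector; eps[1] seeds the
# stationary initial value.
ar1_from_noise <- function(phi, eps) {
  if (!is.numeric(phi) || length(phi) != 1L || abs(phi) >= 1)
    stop("generate_ar1: |phi| must be < 1 (stationarity)")
  T <- length(eps)
  x <- numeric(T)
  x[1] <- eps[1] / sqrt(1 - phi^2)
  for (t in seq_len(T - 1L)) x[t + 1L] <- phi * x[t] + eps[t + 1L]
  x
}

#' Rescale a series to exact sample mean and variance
#'
#' Positive-slope affine map standardizing by the sample standard deviation,
#' so the output's sample mean equals `mu` and its sample variance equals
#' `sigma2` exactly (not just in expectation). Rank order and the sample
#' lag-1 autocorrelation of the input are preserved.
#'
#' @param x Numeric series.
#' @param mu Target sample mean.
#' @param sigma2 Target sample variance (>= 0); `sigma2 = 0` returns the
#'   constant series `mu`.
#' @return Rescaled series, same length as `x`.
#' @export
rescale_to_moments <- function(x, mu, sigma2) {
  if (sigma2 < 0) stop("rescale_to_moments: sigma2 must be >= 0")
  if (sigma2 == 0) return(rep(mu, length(x)))
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("rescale_to_moments: constant series cannot be scaled to sigma2 > 0")
  mu + sqrt(sigma2) * (x - mean(x)) / s
}

#' Proportional manipulation of a baseline variance
#'
#' The target variance of a driver is its baseline variance multiplied by the
#' proportional-variance level: `sigma2 = sigma2_init * sigma2_prop`. Levels
#' below 1 shrink, above 1 inflate, the environmental variance relative to
#' the published model.
#'
#' @param sigma2_init Baseline (published) driver variance, >= 0.
#' @param sigma2_prop Proportional-variance multiplier, >= 0.
#' @return The product.
#' @export
proportional_target_variance <- function(sigma2_init, sigma2_prop) {
  if (any(sigma2_init < 0) || any(sigma2_prop < 0))
    stop("proportional_target_variance: inputs must be >= 0")
  sigma2_init * sigma2_prop
}

#' Generate the environmental driver matrix for one landscape cell
#'
#' One independent AR(1) series per declared driver, each rescaled to the
#' driver's long-run mean and to `sigma2_init * sigma2_prop` exactly. The
#' same `phi` and the same proportional-variance level apply to all drivers.
#' Child seeds are derived deterministically from `seed` and the driver
#' index, so the full matrix is reproducible from `seed` alone.
#'
#' @param ipm An [env_ipm()] declaring the drivers.
#' @param phi Autocorrelation level, `|phi| < 1`.
#' @param sigma2_prop Proportional-variance level.
#' @param T Series length.
#' @param seed Integer master seed.
#' @return `T x d` matrix, columns named and ordered by driver declaration.
#' @export
generate_driver_matrix <- function(ipm, phi, sigma2_prop, T, seed) {
  stopifnot(inherits(ipm, "env_ipm"))
  dn <- driver_names(ipm)
  if (length(dn) == 0) stop("generate_driver_matrix: model declares no drivers")
  env <- matrix(0, nrow = T, ncol = length(dn),
                dimnames = list(NULL, dn))
  for (k in seq_along(dn)) {
    x <- generate_ar1(phi, T, child_seed(seed, k))
    target <- proportional_target_variance(ipm$drivers$sigma2_init[k],
                                           sigma2_prop)
    env[, k] <- rescale_to_moments(x, ipm$drivers$mu[k], target)
  }
  env
}
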