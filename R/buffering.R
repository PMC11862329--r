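#' Perturb the sample variance of a timeseries
#'
#' Multiplies deviations from the sample mean by `sqrt(1 + delta)`:
#' `a'[t] = mean(a) + (a[t] - mean(a)) * sqrt(1 + delta)`. The sample mean is
#' preserved exactly and the sample variance is multiplied by `(1 + delta)`
#' exactly. A constant series is a fixed point (returned unchanged).
#'
#' @param x Numeric series, length >= 2.
#' @param delta Proportional variance increase, > 0 (default 1e-5).
#' @return Perturbed series.
#' @export
perturb_series_variance <- function(x, delta = 1e-5) {
  if (length(x) < 2L) stop("perturb_series_variance: length must be >= 2")
  if (delta <= 0) stop("perturb_series_variance: delta must be > 0")
  m <- mean(x)
  m + (x - m) * sqrt(1 + delta)
}

#' Numerical stochastic elasticities of variance
#'
#' For each kernel element `(i, j)` with nonzero temporal variance, the
#' element's timeseries `a_ij,t` is variance-perturbed by the proportional
#' amount `delta`, the population is re-projected through the otherwise
#' identical kernel sequence with the identical initial vector and burn-in
#' (common random numbers), and the elasticity is the weighted finite
#' difference
#' `E_ij = (var(a_ij,t) / lambda_s) * (lambda_s* - lambda_s) / (delta * var(a_ij,t))`.
#' Elements with zero temporal variance contribute exactly 0. The sum over
#' all elements, `sum_E`, is the demographic-buffering measure: it is
#' negative in practice (temporal variance costs growth), and values closer
#' to 0 indicate a more buffered population.
#'
#' @param kernels A [kernel_sequence()].
#' @param n0 Initial size distribution shared by all projections.
#' @param burn_in Increments discarded before averaging (default 200).
#' @param delta Proportional variance perturbation (default 1e-5).
#' @param var_tol Threshold below which an element's temporal variance is
#'   treated as exactly zero (default 1e-300).
#' @param keep_perturbed Retain the per-element perturbed growth rates
#'   `lambda_s*`? Default `FALSE`.
#' @return Object of class `elasticity_result`: `E` (n x n matrix), `sum_E`,
#'   `lambda_s`, `delta`, and `lambda_s_pert` when requested.
#' @export
stochastic_elasticity_matrix <- function(kernels, n0, burn_in = 200,
                                         delta = 1e-5, var_tol = 1e-300,
                                         keep_perturbed = FALSE) {
  stopifnot(inherits(kernels, "kernel_sequence"))
  res <- .elasticity_sweep_cpp(kernels$K, kernels$K, as.numeric(n0),
                               as.integer(burn_in), delta, var_tol,
                               keep_perturbed)
  if (res$n_negative > 0)
    warning("stochastic_elasticity_matrix: ", res$n_negative,
            " element series changed sign under perturbation ",
            "(degenerate elements)")
  structure(list(E = res$E, sum_E = sum(res$E), lambda_s = res$lambda_s,
                 delta = delta,
                 lambda_s_pert = if (keep_perturbed) res$lambda_s_pert),
            class = "elasticity_result")
}

#' Subkernel stochastic elasticities of variance
#'
#' Repeats the per-element variance perturbation restricted to the
#' progression subkernel `P` (survival-dependent size transitions) and to
#' the fertility subkernel `F` (per-capita recruitment): each perturbed
#' element series is a `P` (resp. `F`) series, the other subkernel's series
#' stay fixed, and the full kernel is rebuilt as their sum for projection.
#'
#' @inheritParams stochastic_elasticity_matrix
#' @return List with `sum_E_P`, `sum_E_F`, `pf_contribution`
#'   (`sum_E_P - sum_E_F`), the per-element matrices `E_P`, `E_F`, and
#'   `lambda_s`.
#' @export
subkernel_elasticities <- function(kernels, n0, burn_in = 200, delta = 1e-5,
                                   var_tol = 1e-300) {
  stopifnot(inherits(kernels, "kernel_sequence"))
  n0 <- as.numeric(n0)
  rp <- .elasticity_sweep_cpp(kernels$K, kernels$P, n0,
                              as.integer(burn_in), delta, var_tol, FALSE)
  rf <- .elasticity_sweep_cpp(kernels$K, kernels$F, n0,
                              as.integer(burn_in), delta, var_tol, FALSE)
  sum_E_P <- sum(rp$E)
  sum_E_F <- sum(rf$E)
  list(sum_E_P = sum_E_P, sum_E_F = sum_E_F,
       pf_contribution = pf_contribution(sum_E_P, sum_E_F),
       E_P = rp$E, E_F = rf$E, lambda_s = rp$lambda_s)
}

#' Progression-minus-fertility contribution
#'
#' The difference of the subkernel summed elasticities of variance,
#' `sum_E_P - sum_E_F`. Positive values indicate that proportional variance
#' in progression rates is more costly to `lambda_s` than proportional
#' variance in fertility rates; negative values the reverse.
#'
#' @param sum_E_P,sum_E_F Subkernel summed elasticities (finite scalars).
#' @return The difference.
#' @export
pf_contribution <- function(sum_E_P, sum_E_F) {
  stopifnot(is.finite(sum_E_P), is.finite(sum_E_F))
  sum_E_P - sum_E_F
}

#' Per-stage buffering profile
#'
#' Column sums of the elasticity matrix: the buffering value associated with
#' stage `j` aggregates the variance elasticities of all transitions out of
#' stage `j`. The profile sums to `sum_E`.
#'
#' @param E Square elasticity matrix (or an `elasticity_result`).
#' @return Numeric vector of length `n_mesh`.
#' @export
stage_buffering_profile <- function(E) {
  if (inherits(E, "elasticity_result")) E <- E$E
  E <- as.matrix(E)
  if (nrow(E) != ncol(E)) stop("stage_buffering_profile: E must be square")
  colSums(E)
}
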