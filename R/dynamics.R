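#' Project a population through a kernel sequence
#'
#' Iterates `n[t+1] = A[t] %*% n[t]` with per-step renormalization of the
#' state vector to total 1 (for numerical stability over long horizons),
#' while accumulating the exact log growth increments
#' `log(N[t+1]/N[t])` of the unnormalized product.
#'
#' @param kernels A [kernel_sequence()].
#' @param n0 Nonnegative, nonzero initial size distribution (length
#'   `n_mesh`).
#' @param keep_states Retain the normalized state at every step? Default
#'   `FALSE` (only increments and totals are kept).
#' @return Object of class `pop_trajectory`: `log_increments` (length `T`),
#'   `totals` (unnormalized population totals `N[1..T+1]`), and optionally
#'   `states` (`n_mesh x (T+1)` matrix of normalized states).
#' @export
project <- function(kernels, n0, keep_states = FALSE) {
  stopifnot(inherits(kernels, "kernel_sequence"))
  A <- kernels$K
  n <- dim(A)[1]
  T_ <- dim(A)[3]
  n0 <- as.numeric(n0)
  if (length(n0) != n) stop("project: n0 has wrong length")
  if (any(n0 < 0) || sum(n0) <= 0)
    stop("project: n0 must be nonnegative and nonzero")
  tot0 <- sum(n0)
  x <- n0 / tot0
  inc <- numeric(T_)
  states <- if (keep_states) matrix(0, n, T_ + 1L) else NULL
  if (keep_states) states[, 1L] <- x
  for (t in seq_len(T_)) {
    v <- as.vector(A[, , t] %*% x)
    s <- sum(v)
    if (!is.finite(s) || s <= 0)
      stop("project: degenerate trajectory (total reached 0) at step ", t)
    inc[t] <- log(s)
    x <- v / s
    if (keep_states) states[, t + 1L] <- x
  }
  structure(list(log_increments = inc,
                 totals = tot0 * exp(c(0, cumsum(inc))),
                 states = states),
            class = "pop_trajectory")
}

#' Stochastic growth rate from a trajectory
#'
#' `lambda_s = exp(mean log(N[t+1]/N[t]))` over post-burn-in increments
#' (increment indices strictly greater than `burn_in`), discarding the
#' initial transient.
#'
#' @param traj A [project()] result, or a numeric vector of log increments.
#' @param burn_in Number of leading increments to discard (default 200).
#' @return `lambda_s` (scalar > 0).
#' @export
stochastic_growth_rate <- function(traj, burn_in = 200) {
  inc <- if (inherits(traj, "pop_trajectory")) traj$log_increments
         else as.numeric(traj)
  if (burn_in >= length(inc))
    stop("stochastic_growth_rate: burn_in must be < number of increments")
  kept <- inc[(burn_in + 1L):length(inc)]
  if (any(!is.finite(kept)))
    stop("stochastic_growth_rate: non-finite log increments")
  exp(mean(kept))
}

#' Average size distribution under a stochastic kernel sequence
#'
#' Iterates many random initial size distributions (uniform on the simplex)
#' through the kernel sequence with per-step normalization, and averages the
#' normalized states over all retained (trajectory, timestep) pairs —
#' timesteps after the burn-in. The result is the time- and
#' replicate-averaged population structure (ASD).
#'
#' @param kernels A [kernel_sequence()].
#' @param n_inits Number of random initial distributions (default 1000).
#' @param burn_in Leading steps discarded (default 200).
#' @param seed Integer seed for the initial distributions.
#' @return Nonnegative vector summing to 1 (length `n_mesh`).
#' @export
average_size_distribution <- function(kernels, n_inits = 1000, burn_in = 200,
                                      seed = 1L) {
  stopifnot(inherits(kernels, "kernel_sequence"))
  A <- kernels$K
  n <- dim(A)[1]
  T_ <- dim(A)[3]
  if (burn_in >= T_)
    stop("average_size_distribution: burn_in must be < sequence length")
  # Dirichlet(1,...,1) draws: normalized Exp(1) columns
  S <- with_seed(seed, matrix(rexp(n * n_inits), nrow = n))
  S <- sweep(S, 2, colSums(S), "/")
  acc <- numeric(n)
  for (t in seq_len(T_)) {
    S <- A[, , t] %*% S
    cs <- colSums(S)
    if (any(!is.finite(cs)) || any(cs <= 0))
      stop("average_size_distribution: degenerate trajectory at step ", t)
    S <- sweep(S, 2, cs, "/")
    if (t > burn_in) acc <- acc + rowSums(S)
  }
  asd <- acc / ((T_ - burn_in) * n_inits)
  asd / sum(asd)
}
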