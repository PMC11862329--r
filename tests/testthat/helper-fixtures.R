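# Shared fixtures, all built in code at test time.

# Kernel sequence of 1x1 "kernels" from a numeric vector.
scalar_sequence <- function(values) {
  kernel_sequence(array(values, c(1, 1, length(values))))
}

# Geometric-mean stochastic growth rate of a scalar kernel series after
# burn-in: the closed form lambda_s for 1x1 sequences.
geomean_lambda_s <- function(values, burn_in) {
  exp(mean(log(values[(burn_in + 1):length(values)])))
}

# Brute-force scalar elasticity oracle: explicitly variance-perturb the
# series, recompute lambda_s as the geometric mean, form Eq-7's weighted
# finite difference. Independent of the package's projection machinery.
scalar_elasticity_oracle <- function(values, burn_in, delta = 1e-5) {
  lam <- geomean_lambda_s(values, burn_in)
  m <- mean(values)
  pert <- m + (values - m) * sqrt(1 + delta)
  lam_star <- geomean_lambda_s(pert, burn_in)
  v <- var(values)
  (v / lam) * ((lam_star - lam) / (delta * v))
}

# Reference species on a coarser mesh for fast stochastic tests; the model
# coefficients are identical to make_reference_species().
reference_species_coarse <- function(n_mesh = 40) {
  ipm <- make_reference_species()
  ipm$mesh <- size_mesh(ipm$mesh$alpha, ipm$mesh$omega, n_mesh)
  ipm
}

# Tiny fast IPM for orchestration tests (20 cells, short series still mix).
tiny_ipm <- function() {
  ipm <- make_reference_species()
  ipm$mesh <- size_mesh(0, 10, 20)
  ipm
}

uniform_n0 <- function(n) rep(1 / n, n)
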