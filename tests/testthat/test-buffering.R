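test_that("variance perturbation preserves the mean and scales the variance", {
  expect_identical(perturb_series_variance(c(3, 3, 3)), c(3, 3, 3))
  expect_equal(perturb_series_variance(c(0, 2), delta = 1),
               c(1 - sqrt(2), 1 + sqrt(2)))
  set.seed(8)
  x <- rnorm(200, 5, 2)
  y <- perturb_series_variance(x, delta = 1e-5)
  expect_lt(abs(mean(y) - mean(x)), 1e-14 * abs(mean(x)))
  expect_equal(var(y), var(x) * (1 + 1e-5), tolerance = 1e-12)
  expect_error(perturb_series_variance(1), "length")
  expect_error(perturb_series_variance(c(1, 2), delta = 0), "delta")
})

test_that("constant kernel sequences have zero elasticities everywhere", {
  K <- matrix(c(0.4, 0.1, 0.6, 0.5), 2)
  sq <- kernel_sequence(array(rep(K, 50), c(2, 2, 50)))
  el <- stochastic_elasticity_matrix(sq, c(0.5, 0.5), burn_in = 10)
  expect_identical(el$E, matrix(0, 2, 2))
  expect_identical(el$sum_E, 0)
})

test_that("scalar elasticities match the brute-force perturbed geometric mean", {
  sigma <- 0.05
  vals <- rep(c(exp(sigma), exp(-sigma)), 200)
  sq <- scalar_sequence(vals)
  el <- stochastic_elasticity_matrix(sq, 1, burn_in = 100)
  oracle <- scalar_elasticity_oracle(vals, burn_in = 100)
  expect_equal(el$E[1, 1], oracle, tolerance = 1e-8)
  expect_equal(el$lambda_s, geomean_lambda_s(vals, 100), tolerance = 1e-13)
  # closed form for the alternating series: E = -sinh(sigma)^2 / 2 at small delta
  expect_equal(el$E[1, 1], -sinh(sigma)^2 / 2, tolerance = 1e-4)
})

test_that("the weighted and simplified elasticity forms agree", {
  set.seed(13)
  A <- array(runif(3 * 3 * 80, 0.1, 0.9), c(3, 3, 80))
  sq <- kernel_sequence(A)
  el <- stochastic_elasticity_matrix(sq, rep(1 / 3, 3), burn_in = 20,
                                     keep_perturbed = TRUE)
  alt <- (el$lambda_s_pert - el$lambda_s) / (el$delta * el$lambda_s)
  alt[is.na(alt)] <- 0
  expect_equal(el$E, alt, tolerance = 1e-12)
  expect_equal(sum(el$E), el$sum_E, tolerance = 1e-10)
})

test_that("subkernel elasticities vanish for F == 0 and add up on disjoint supports", {
  set.seed(21)
  # disjoint supports: P occupies the lower triangle, F the strict upper
  n <- 3; T_ <- 60
  P <- array(0, c(n, n, T_)); F_ <- array(0, c(n, n, T_))
  for (t in 1:T_) {
    M <- matrix(runif(n * n, 0.1, 0.8), n)
    P[, , t] <- M * lower.tri(M, diag = TRUE)
    F_[, , t] <- M * upper.tri(M)
  }
  sq <- kernel_sequence(P + F_, P, F_)
  n0 <- rep(1 / n, n)
  el_k <- stochastic_elasticity_matrix(sq, n0, burn_in = 10)
  sk <- subkernel_elasticities(sq, n0, burn_in = 10)
  expect_equal(sk$sum_E_P + sk$sum_E_F, el_k$sum_E, tolerance = 1e-8)
  expect_equal(sk$pf_contribution, sk$sum_E_P - sk$sum_E_F)

  # F identically zero
  sq0 <- kernel_sequence(P, P, array(0, dim(P)))
  sk0 <- subkernel_elasticities(sq0, n0, burn_in = 10)
  expect_identical(sk0$sum_E_F, 0)
})

test_that("a constant fertility subkernel leaves all variance cost in P", {
  # scalar model split K = P + F with F constant in time
  pvals <- rep(c(0.8, 1.2), 100)
  fvals <- rep(0.3, 200)
  K <- array(pvals + fvals, c(1, 1, 200))
  sq <- kernel_sequence(K, array(pvals, c(1, 1, 200)),
                        array(fvals, c(1, 1, 200)))
  sk <- subkernel_elasticities(sq, 1, burn_in = 50)
  el_k <- stochastic_elasticity_matrix(sq, 1, burn_in = 50)
  expect_identical(sk$sum_E_F, 0)
  # K deviations equal P deviations, so the K-level sum transfers exactly
  expect_equal(sk$sum_E_P, el_k$sum_E, tolerance = 1e-10)
})

test_that("pf contribution is the subkernel difference", {
  expect_equal(pf_contribution(-0.2, -0.2), 0)
  expect_equal(pf_contribution(-0.1, -0.3), 0.2)
  expect_equal(pf_contribution(-0.3, -0.1), -0.2)
})

test_that("stage profile takes column sums and conserves the total", {
  expect_equal(stage_buffering_profile(matrix(0, 3, 3)), rep(0, 3))
  E <- matrix(0, 4, 4); E[2, 3] <- -0.1
  expect_equal(stage_buffering_profile(E), c(0, 0, -0.1, 0))
  set.seed(2)
  E2 <- matrix(rnorm(25), 5)
  expect_equal(sum(stage_buffering_profile(E2)), sum(E2), tolerance = 1e-12)
})

test_that("more environmental variance means less buffering (reference species)", {
  ipm <- reference_species_coarse()
  n0 <- uniform_n0(40)
  sum_e <- vapply(c(0.9, 1.1), function(s2p) {
    env <- generate_driver_matrix(ipm, 0, s2p, 1000, 7)
    sq <- build_kernel_sequence(ipm, env)
    suppressWarnings(stochastic_elasticity_matrix(sq, n0))$sum_E
  }, numeric(1))
  expect_lt(sum_e[2], sum_e[1])
  expect_lt(sum_e[1], 0)
})

test_that("summed variance elasticities approximate the log growth-rate deficit", {
  # small-noise Tuljapurkar-type consistency at a quarter of the baseline
  # driver variance, averaged over independent environment realizations
  # (the expectation is what the approximation concerns; a single
  # realization carries a finite-series linear sampling term)
  ipm <- reference_species_coarse()
  n0 <- uniform_n0(40)
  se <- dl <- numeric(5)
  for (s in 1:5) {
    env <- generate_driver_matrix(ipm, 0, 0.25, 1000, s)
    sq <- build_kernel_sequence(ipm, env)
    el <- suppressWarnings(stochastic_elasticity_matrix(sq, n0))
    se[s] <- el$sum_E
    dl[s] <- log(el$lambda_s) - log(dominant_eigenvalue(mean_kernel(sq)))
  }
  expect_lt(abs(mean(se) - mean(dl)) / abs(mean(se)), 0.15)
})
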