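test_that("size mesh midpoints follow the midpoint-rule formula", {
  m <- size_mesh(0, 10, 50)
  expect_equal(m$width, 0.2)
  expect_equal(m$midpoints[1], 0.1)
  expect_equal(m$midpoints[50], 9.9)
  expect_equal(m$midpoints, 0 + (1:50 - 0.5) * 0.2)
  expect_error(size_mesh(5, 5, 10), "alpha")
  expect_error(size_mesh(0, 1, 1), "n_mesh")
})

test_that("predictor evaluation applies the inverse link", {
  expect_equal(evaluate_predictor(linear_predictor(0.7), z = 1), 0.7)
  expect_equal(evaluate_predictor(linear_predictor(0, link = "logit"), 1), 0.5)
  expect_equal(evaluate_predictor(linear_predictor(log(2), link = "log"), 1), 2)
  sp <- linear_predictor(1, c(size = 2, size2 = 0.5, temp = 1,
                              "temp:size" = 0.25), link = "identity")
  # eta = 1 + 2*3 + 0.5*9 + 1*2 + 0.25*6 = 15
  expect_equal(evaluate_predictor(sp, 3, c(temp = 2)), 15)
  bad <- linear_predictor(0, c(humidity = 1))
  expect_error(evaluate_predictor(bad, 1, c(temp = 2)), "humidity")
})

test_that("kernel construction composes P and F correctly", {
  ipm <- make_reference_species()
  ks <- build_kernel(ipm, c(env = 0))
  expect_true(all(ks$P >= 0) && all(ks$F >= 0))
  expect_identical(ks$K, ks$P + ks$F)
  expect_true(all(colSums(ks$P) <=
                  max(evaluate_predictor(ipm$survival, ipm$mesh$midpoints,
                                         c(env = 0))) + 1e-12))

  # survival forced to zero: P vanishes
  dead <- ipm
  dead$survival <- linear_predictor(-1e3, link = "logit")
  expect_equal(max(abs(build_kernel(dead, c(env = 0))$P)), 0)

  # fertility forced to zero: K reduces to P
  sterile <- ipm
  sterile$offspring <- linear_predictor(-1e3, link = "log")
  kss <- build_kernel(sterile, c(env = 0))
  expect_equal(kss$K, kss$P)

  expect_error(build_kernel(ipm, c(wrong = 0)), "missing driver")
})

test_that("growth columns integrate to 1 when transitions stay interior", {
  # survival == 1 and growth mean >= 3 SD from both bounds: the midpoint-rule
  # Gaussian integral over the mesh captures essentially all mass
  ipm <- make_reference_species()
  ipm$survival <- linear_predictor(1e3, link = "logit") # s == 1
  ipm$growth_mean <- linear_predictor(5, link = "identity") # centre of [0,10]
  ipm$growth_sd <- 1 # 5 SD from each bound
  ipm$offspring <- linear_predictor(-1e3, link = "log")
  ks <- build_kernel(ipm, c(env = 0))
  expect_true(all(abs(colSums(ks$P) - 1) < 1e-6))
})

test_that("kernel construction is deterministic", {
  ipm <- make_reference_species()
  k1 <- build_kernel(ipm, c(env = 0.3))
  k2 <- build_kernel(ipm, c(env = 0.3))
  expect_identical(k1, k2)
})

test_that("mean kernel equals the elementwise arithmetic mean", {
  expect_equal(mean_kernel(scalar_sequence(c(0, 2))), matrix(1))
  const <- kernel_sequence(array(rep(diag(3), 4), c(3, 3, 4)))
  expect_equal(mean_kernel(const), diag(3))
  set.seed(11)
  A <- array(runif(3 * 3 * 7), c(3, 3, 7))
  ref <- matrix(0, 3, 3)
  for (t in 1:7) ref <- ref + A[, , t]
  expect_equal(mean_kernel(kernel_sequence(A)), ref / 7, tolerance = 1e-14)
})

test_that("dominant eigenvalue handles periodic and symmetric cases", {
  expect_equal(dominant_eigenvalue(matrix(c(0, 0.5, 2, 0), 2)), 1,
               tolerance = 1e-9)
  expect_equal(dominant_eigenvalue(diag(4)), 1, tolerance = 1e-9)
  expect_equal(dominant_eigenvalue(matrix(1, 2, 2)), 2, tolerance = 1e-9)
  expect_error(dominant_eigenvalue(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("kernel sequences match per-timestep kernels and env rows", {
  ipm <- tiny_ipm()
  env <- matrix(c(0, 0.5, -0.5, 1, 0), ncol = 1,
                dimnames = list(NULL, "env"))
  sq <- build_kernel_sequence(ipm, env)
  expect_equal(length(sq), 5L)
  for (t in 1:5) {
    ks <- build_kernel(ipm, env[t, ])
    expect_identical(sq$K[, , t], ks$K)
    expect_identical(sq$P[, , t] + sq$F[, , t], sq$K[, , t])
  }
  # constant env: identical kernels
  sqc <- build_kernel_sequence(ipm, matrix(0.2, 4, 1,
                                           dimnames = list(NULL, "env")))
  expect_identical(sqc$K[, , 1], sqc$K[, , 4])
  expect_error(build_kernel_sequence(ipm, matrix(0, 3, 2)), "driver")
})

test_that("element series accessor returns the stored timeseries", {
  set.seed(3)
  A <- array(runif(2 * 2 * 6), c(2, 2, 6))
  sq <- kernel_sequence(A)
  expect_equal(element_series(sq, 2, 1), A[2, 1, ])
})

test_that("discretization is converged: doubling the mesh moves lambda_1 < 1%", {
  ipm <- make_reference_species()
  lam60 <- dominant_eigenvalue(build_kernel(ipm)$K)
  ipm$mesh <- size_mesh(0, 10, 120)
  lam120 <- dominant_eigenvalue(build_kernel(ipm)$K)
  expect_lt(abs(lam120 - lam60) / lam60, 0.01)
})
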