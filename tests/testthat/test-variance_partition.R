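grid_xy <- function() {
  g <- expand.grid(phi = seq(-0.8, 0.8, length.out = 15),
                   v = seq(0.9, 1.1, length.out = 15))
  list(phi = g$phi, v = g$v)
}

test_that("design matrices centre predictors and detect collinearity", {
  g <- grid_xy()
  X <- build_design(g$phi, g$v, 1, 1, interaction = FALSE)
  expect_identical(colnames(X), c("(Intercept)", "auto1", "var1"))
  Xi <- build_design(g$phi, g$v, 2, 1, interaction = TRUE)
  expect_equal(Xi[, "auto_x_var"],
               (g$phi - mean(g$phi)) * (g$v - mean(g$v)))
  expect_true(all(abs(colMeans(Xi[, c("auto1", "var1", "auto_x_var")])) < 1e-12))
  expect_error(build_design(rep(1, 30), g$v[1:30], 2, 1), "collinear")
})

test_that("OLS matches the normal-equations oracle", {
  set.seed(6)
  X <- cbind(1, matrix(rnorm(60 * 3), 60))
  beta <- c(2, -1, 0.5, 3)
  y <- as.vector(X %*% beta)
  fit <- fit_ols(X, y)
  expect_lt(fit$rss, 1e-16 * sum(y^2))
  yn <- y + rnorm(60)
  fit2 <- fit_ols(X, yn)
  oracle <- solve(t(X) %*% X, t(X) %*% yn)
  expect_equal(unname(fit2$coefficients), as.vector(oracle),
               tolerance = 1e-8)
  # response orthogonal to the non-intercept columns
  Xc <- cbind(1, scale(matrix(rnorm(40 * 2), 40), scale = FALSE))
  y0 <- rep(4, 40)
  fit3 <- fit_ols(Xc, y0)
  expect_equal(unname(fit3$coefficients), c(4, 0, 0), tolerance = 1e-10)
})

test_that("AIC selection finds the generating polynomial and breaks ties small", {
  g <- grid_xy()
  # noiseless linear response in variance: floored-RSS ties resolve to the
  # smallest candidate
  y_lin <- 2 + 3 * (g$v - mean(g$v))
  sel <- aic_select(g$phi, g$v, y_lin)$selected
  expect_equal(sel$degree_auto, 1)
  expect_equal(sel$degree_var, 1)
  expect_false(sel$interaction)
  # cubic autocorrelation signal with small noise
  set.seed(17)
  y_cub <- (g$phi - mean(g$phi))^3 + rnorm(length(g$phi), 0, 0.01)
  sel2 <- aic_select(g$phi, g$v, y_cub)$selected
  expect_equal(sel2$degree_auto, 3)
  # invariance to adding a constant
  sel3 <- aic_select(g$phi, g$v, y_cub + 100)$selected
  expect_equal(sel3[c("degree_auto", "degree_var", "interaction")],
               sel2[c("degree_auto", "degree_var", "interaction")])
  expect_error(aic_select(1:5, 1:5, 1:5), "10 cells")
})

test_that("sequential shares decompose the total sum of squares", {
  g <- grid_xy()
  y_var <- 2 * (g$v - mean(g$v))
  p <- partition_contributions(g$phi, g$v, y_var)
  expect_equal(p$share_var, 1, tolerance = 1e-10)
  expect_equal(p$share_auto + p$share_interaction + p$share_residual, 0,
               tolerance = 1e-10)
  set.seed(23)
  y <- rnorm(length(g$phi))
  pr <- partition_contributions(g$phi, g$v, y)
  expect_equal(pr$share_auto + pr$share_var + pr$share_interaction +
                 pr$share_residual, 1, tolerance = 1e-10)
  expect_equal(pr$r_squared, 1 - pr$share_residual, tolerance = 1e-12)
  expect_error(partition_contributions(g$phi, g$v, rep(1, length(g$phi))),
               "constant")
})

test_that("block shares are order-invariant on the factorial grid", {
  g <- grid_xy()
  set.seed(31)
  y <- 0.5 * (g$phi - mean(g$phi)) - 2 * (g$v - mean(g$v))^2 +
    rnorm(length(g$phi), 0, 0.05)
  sel <- data.frame(degree_auto = 2, degree_var = 2, interaction = TRUE)
  p1 <- partition_contributions(g$phi, g$v, y, sel)
  # swap the roles of the predictors: the variance block now enters first
  sel_sw <- data.frame(degree_auto = 2, degree_var = 2, interaction = TRUE)
  p2 <- partition_contributions(g$v, g$phi, y, sel_sw)
  expect_equal(p1$share_auto, p2$share_var, tolerance = 1e-10)
  expect_equal(p1$share_var, p2$share_auto, tolerance = 1e-10)
  expect_equal(p1$share_residual, p2$share_residual, tolerance = 1e-10)
})
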