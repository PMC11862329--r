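#' Polynomial design matrix for landscape responses
#'
#' Centers both predictors (autocorrelation and proportional variance) at
#' their grid means, then builds raw polynomial columns up to the requested
#' degrees plus an optional linear-by-linear interaction. On a fully
#' factorial grid the centered autocorrelation block and variance block are
#' mutually orthogonal, so block-level sums of squares do not depend on
#' block entry order.
#'
#' @param phi Autocorrelation values, one per cell.
#' @param v Proportional-variance values, one per cell.
#' @param degree_auto,degree_var Polynomial degree per predictor (1-3).
#' @param interaction Include the centered product term? Default `FALSE`.
#' @return Design matrix with an intercept column and named polynomial
#'   columns `auto1..`, `var1..`, and `auto_x_var` when requested.
#' @export
build_design <- function(phi, v, degree_auto = 1L, degree_var = 1L,
                         interaction = FALSE) {
  if (length(phi) != length(v)) stop("build_design: length mismatch")
  a <- phi - mean(phi)
  w <- v - mean(v)
  cols <- list("(Intercept)" = rep(1, length(a)))
  for (p in seq_len(degree_auto)) cols[[paste0("auto", p)]] <- a^p
  for (p in seq_len(degree_var)) cols[[paste0("var", p)]] <- w^p
  if (interaction) cols[["auto_x_var"]] <- a * w
  X <- do.call(cbind, cols)
  if (nrow(X) < ncol(X))
    stop("build_design: fewer rows than columns")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("build_design: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  X
}

#' Ordinary least squares fit
#'
#' @param X Full-column-rank design matrix.
#' @param y Response vector.
#' @return List with `coefficients`, `fitted`, and `rss` (the minimized
#'   residual sum of squares).
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("fit_ols: dimension mismatch")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("fit_ols: rank-deficient design")
  beta <- qr.coef(qrX, y)
  fitted <- as.vector(X %*% beta)
  list(coefficients = beta, fitted = fitted, rss = sum((y - fitted)^2))
}

# All 18 candidate polynomial models: degrees 1-3 per predictor, with and
# without the linear interaction; both predictors always present.
candidate_grid <- function() {
  g <- expand.grid(degree_auto = 1:3, degree_var = 1:3, interaction = c(FALSE, TRUE))
  g$k <- g$degree_auto + g$degree_var + as.integer(g$interaction)
  g
}

#' AIC selection over the polynomial candidate suite
#'
#' Fits all 18 candidate models (degree 1-3 per predictor, optional
#' interaction) and selects the minimum-AIC one. AIC uses the Gaussian
#' log-likelihood up to additive constants,
#' `AIC = n * log(rss / n) + 2 * (k + 2)` with `k` non-intercept terms
#' (the `+ 2` counts the intercept and the error variance); the RSS is
#' floored at `n * 1e-12 * var(y)` so noiseless responses keep AIC finite.
#' Exact AIC ties resolve to the fewest parameters, then the lowest
#' autocorrelation degree, then the lowest variance degree.
#'
#' @param phi,v Predictor values, one per grid cell (n >= 10).
#' @param y Response values.
#' @return List: `selected` (one-row data frame with degrees, interaction
#'   flag, `k`, `rss`, `aic`) and `table` (all 18 candidates, AIC-sorted).
#' @export
aic_select <- function(phi, v, y) {
  n <- length(y)
  if (n < 10L) stop("aic_select: need at least 10 cells")
  cand <- candidate_grid()
  cand$rss <- NA_real_
  cand$aic <- NA_real_
  floor_rss <- n * 1e-12 * var(y)
  for (i in seq_len(nrow(cand))) {
    X <- build_design(phi, v, cand$degree_auto[i], cand$degree_var[i],
                      cand$interaction[i])
    fit <- fit_ols(X, y)
    cand$rss[i] <- fit$rss
    cand$aic[i] <- n * log(max(fit$rss, floor_rss) / n) + 2 * (cand$k[i] + 2)
  }
  ord <- order(cand$aic, cand$k, cand$degree_auto, cand$degree_var)
  cand <- cand[ord, ]
  rownames(cand) <- NULL
  list(selected = cand[1, ], table = cand)
}

#' Variance partition of a landscape response
#'
#' Sequential (Type I) sums of squares for the selected polynomial model
#' with fixed entry order: autocorrelation terms by ascending degree, then
#' proportional-variance terms, then the interaction. Block sums of squares
#' are divided by the total sum of squares, giving the share of landscape
#' variance attributable to each environmental component; the residual share
#' is `rss / TSS` and all four shares sum to 1.
#'
#' @param phi,v Predictor values per cell.
#' @param y Response values (must not be constant).
#' @param selected Selected model (one-row data frame from [aic_select()];
#'   default refits the selection).
#' @return List of class `partition_result`: `r_squared`, `share_auto`,
#'   `share_var`, `share_interaction`, `share_residual`, `selected`.
#' @export
partition_contributions <- function(phi, v, y, selected = NULL) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("partition_contributions: constant response (TSS = 0)")
  if (is.null(selected)) selected <- aic_select(phi, v, y)$selected
  da <- selected$degree_auto
  dv <- selected$degree_var
  inter <- isTRUE(selected$interaction) || selected$interaction == 1
  a <- phi - mean(phi)
  w <- v - mean(v)
  blocks <- list(
    auto = sapply(seq_len(da), function(p) a^p),
    var = sapply(seq_len(dv), function(p) w^p)
  )
  if (inter) blocks$interaction <- matrix(a * w, ncol = 1)

  X <- matrix(1, nrow = length(y), ncol = 1)
  rss_prev <- tss
  ss <- c(auto = 0, var = 0, interaction = 0)
  for (nm in names(blocks)) {
    X <- cbind(X, blocks[[nm]])
    rss_now <- fit_ols(X, y)$rss
    ss[nm] <- rss_prev - rss_now
    rss_prev <- rss_now
  }
  structure(list(
    r_squared = 1 - rss_prev / tss,
    share_auto = ss[["auto"]] / tss,
    share_var = ss[["var"]] / tss,
    share_interaction = ss[["interaction"]] / tss,
    share_residual = rss_prev / tss,
    selected = selected
  ), class = "partition_result")
}

#' Partition a landscape-table response among environmental components
#'
#' Convenience wrapper: AIC-selects the polynomial model for one response
#' column of a [run_landscape()] table and partitions its variance.
#'
#' @param table Landscape table (data frame with `phi` and `sigma2_prop`).
#' @param response Name of the response column.
#' @return A `partition_result` with the full AIC `table` attached.
#' @export
partition_landscape <- function(table, response) {
  if (!response %in% names(table))
    stop("partition_landscape: no column '", response, "'")
  y <- table[[response]]
  sel <- aic_select(table$phi, table$sigma2_prop, y)
  out <- partition_contributions(table$phi, table$sigma2_prop, y,
                                 selected = sel$selected)
  out$aic_table <- sel$table
  out
}
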