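#' Midpoint size mesh
#'
#' Discretizes the continuous size domain `[alpha, omega]` into `n_mesh`
#' equal-width cells; kernel integrals are approximated by the midpoint rule
#' on the cell-center sizes.
#'
#' @param alpha Lower size bound.
#' @param omega Upper size bound (must exceed `alpha`).
#' @param n_mesh Number of midpoint cells (at least 2).
#' @return An object of class `size_mesh` with elements `alpha`, `omega`,
#'   `n_mesh`, `midpoints` (cell-center sizes `z_j = alpha + (j - 1/2) h`) and
#'   `width` (cell width `h`).
#' @examples
#' m <- size_mesh(0, 10, 50)
#' m$midpoints[1] # 0.1
#' @export
size_mesh <- function(alpha, omega, n_mesh) {
  stopifnot(is.numeric(alpha), is.numeric(omega), length(alpha) == 1L,
            length(omega) == 1L)
  if (!(alpha < omega)) stop("size_mesh: alpha must be < omega")
  n_mesh <- as.integer(n_mesh)
  if (is.na(n_mesh) || n_mesh < 2L) stop("size_mesh: n_mesh must be >= 2")
  h <- (omega - alpha) / n_mesh
  structure(
    list(alpha = alpha, omega = omega, n_mesh = n_mesh,
         midpoints = alpha + (seq_len(n_mesh) - 0.5) * h, width = h),
    class = "size_mesh"
  )
}

#' Linear predictor specification for a vital rate
#'
#' A vital-rate regression over size and named environmental drivers.
#' Recognised term names are `"size"`, `"size2"` (size squared), any declared
#' driver name, and `"<driver>:size"` (driver-by-size product).
#'
#' @param intercept Intercept coefficient.
#' @param coefficients Named numeric vector of slope coefficients (may be
#'   empty).
#' @param link One of `"identity"`, `"log"`, `"logit"`; the inverse link is
#'   applied to the linear predictor.
#' @return An object of class `linear_predictor`.
#' @examples
#' surv <- linear_predictor(-1, c(size = 0.5, env = 0.3), link = "logit")
#' evaluate_predictor(surv, z = 2, drivers = c(env = 0))
#' @export
linear_predictor <- function(intercept, coefficients = numeric(0),
                             link = c("identity", "log", "logit")) {
  link <- match.arg(link)
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  coefficients <- unlist(coefficients)
  if (is.null(coefficients)) coefficients <- numeric(0)
  if (length(coefficients) > 0 &&
      (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))))
    stop("linear_predictor: all coefficients must be named")
  structure(list(intercept = unname(intercept),
                 coefficients = coefficients, link = link),
            class = "linear_predictor")
}

inv_link <- function(eta, link) {
  switch(link,
         identity = eta,
         log = exp(eta),
         logit = plogis(eta),
         stop("unknown link: ", link))
}

resolve_variable <- function(name, z, drivers) {
  if (name == "size") return(z)
  if (name == "size2") return(z^2)
  if (name %in% names(drivers)) return(rep_len(drivers[[name]], length(z)))
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  if (length(parts) == 2L) {
    a <- parts[parts != "size"]
    if (length(a) == 1L && "size" %in% parts && a %in% names(drivers))
      return(z * drivers[[a]])
  }
  stop("evaluate_predictor: unresolvable variable '", name, "'")
}

#' Evaluate a vital-rate regression on the response scale
#'
#' @param spec A [linear_predictor()].
#' @param z Size value(s).
#' @param drivers Named list/vector of environmental driver values.
#' @return Response-scale value(s): inverse link applied to
#'   `intercept + sum(coef * variable)`.
#' @export
evaluate_predictor <- function(spec, z, drivers = numeric(0)) {
  stopifnot(inherits(spec, "linear_predictor"))
  drivers <- as.list(drivers)
  eta <- rep_len(spec$intercept, length(z))
  for (nm in names(spec$coefficients)) {
    eta <- eta + spec$coefficients[[nm]] * resolve_variable(nm, z, drivers)
  }
  inv_link(eta, spec$link)
}

#' Environmentally explicit integral projection model
#'
#' Bundles the size mesh, vital-rate regressions and environmental-driver
#' definitions of a parameter-stochastic IPM. Drivers carry their long-run
#' mean `mu` and baseline variance `sigma2_init`; environmental timeseries
#' are generated against these and fed through the regressions to produce a
#' temporal sequence of kernels.
#'
#' @param mesh A [size_mesh()].
#' @param survival [linear_predictor()] for survival probability (logit link).
#' @param growth_mean [linear_predictor()] for expected size next step
#'   (identity link).
#' @param growth_sd Positive residual SD of the Gaussian growth kernel.
#' @param p_repro [linear_predictor()] for reproduction probability (logit
#'   link), or `NULL` for the identity value 1.
#' @param offspring [linear_predictor()] for per-capita offspring count (log
#'   link), or `NULL` for 1.
#' @param recruit_mean [linear_predictor()] (identity link; may reference
#'   drivers but not size) or a single number: mean recruit size.
#' @param recruit_sd Positive SD of the Gaussian recruit-size distribution.
#' @param drivers Data frame with columns `name`, `mu`, `sigma2_init`
#'   declaring every environmental driver referenced by the regressions.
#' @param name Optional model name.
#' @return An object of class `env_ipm`.
#' @seealso [build_kernel()], [make_reference_species()], [read_model()]
#' @export
env_ipm <- function(mesh, survival, growth_mean, growth_sd,
                    p_repro = NULL, offspring = NULL,
                    recruit_mean, recruit_sd, drivers, name = "unnamed") {
  stopifnot(inherits(mesh, "size_mesh"),
            inherits(survival, "linear_predictor"),
            inherits(growth_mean, "linear_predictor"))
  if (!is.numeric(growth_sd) || length(growth_sd) != 1L || growth_sd <= 0)
    stop("env_ipm: growth_sd must be a positive scalar")
  if (!is.numeric(recruit_sd) || length(recruit_sd) != 1L || recruit_sd <= 0)
    stop("env_ipm: recruit_sd must be a positive scalar")
  if (is.numeric(recruit_mean) && length(recruit_mean) == 1L)
    recruit_mean <- linear_predictor(recruit_mean, link = "identity")
  drivers <- as.data.frame(drivers, stringsAsFactors = FALSE)
  if (nrow(drivers) > 0) {
    stopifnot(all(c("name", "mu", "sigma2_init") %in% names(drivers)))
    if (any(drivers$sigma2_init < 0))
      stop("env_ipm: sigma2_init must be >= 0")
    if (anyDuplicated(drivers$name))
      stop("env_ipm: duplicate driver names")
  }
  obj <- structure(
    list(name = name, mesh = mesh, survival = survival,
         growth_mean = growth_mean, growth_sd = growth_sd,
         p_repro = p_repro, offspring = offspring,
         recruit_mean = recruit_mean, recruit_sd = recruit_sd,
         drivers = drivers),
    class = "env_ipm"
  )
  undeclared <- setdiff(referenced_drivers(obj), drivers$name)
  if (length(undeclared) > 0)
    stop("env_ipm: driver(s) referenced but not declared: ",
         paste(undeclared, collapse = ", "))
  obj
}

# Names of drivers referenced by any regression term of the model.
referenced_drivers <- function(ipm) {
  specs <- Filter(Negate(is.null),
                  list(ipm$survival, ipm$growth_mean, ipm$p_repro,
                       ipm$offspring, ipm$recruit_mean))
  vars <- unlist(lapply(specs, function(s) names(s$coefficients)))
  vars <- setdiff(vars, c("size", "size2"))
  unique(sub(":?size:?", "", vars))
}

driver_names <- function(ipm) as.character(ipm$drivers$name)

driver_means <- function(ipm) {
  stats::setNames(as.numeric(ipm$drivers$mu), driver_names(ipm))
}

#' Discretize an IPM into kernel matrices at given driver values
#'
#' Builds the progression subkernel `P` (survival times Gaussian
#' size-transition density, midpoint rule: density at the destination
#' midpoint times cell width), the fertility subkernel `F` (reproduction
#' probability times offspring count times Gaussian recruit-size density) and
#' the full kernel `K = P + F`. Size-transition and recruit densities are
#' truncated at the mesh bounds; mass falling outside is lost unless
#' `renormalize_growth` is set, in which case each growth column is
#' renormalized so the column sum of `P` equals the survival value.
#'
#' @param ipm An [env_ipm()].
#' @param driver_values Named vector covering all declared drivers.
#' @param renormalize_growth Renormalize growth columns (no-eviction
#'   correction)? Default `FALSE`.
#' @return An object of class `kernel_set`: list with matrices `P`, `F`, `K`.
#' @export
build_kernel <- function(ipm, driver_values = driver_means(ipm),
                         renormalize_growth = FALSE) {
  stopifnot(inherits(ipm, "env_ipm"))
  dn <- driver_names(ipm)
  if (length(dn) > 0) {
    driver_values <- unlist(driver_values)
    missing <- setdiff(dn, names(driver_values))
    if (length(missing) > 0)
      stop("build_kernel: missing driver value(s): ",
           paste(missing, collapse = ", "))
  }
  dv <- as.list(driver_values)
  z <- ipm$mesh$midpoints
  h <- ipm$mesh$width
  n <- ipm$mesh$n_mesh

  s <- evaluate_predictor(ipm$survival, z, dv)
  mu_g <- evaluate_predictor(ipm$growth_mean, z, dv)
  # G[i, j]: density of moving from z_j to cell i
  G <- outer(z, mu_g, function(zi, m) dnorm(zi, m, ipm$growth_sd)) * h
  if (renormalize_growth) {
    cs <- colSums(G)
    if (any(cs <= 0)) stop("build_kernel: growth column with zero mass")
    G <- sweep(G, 2, cs, "/")
  }
  P <- sweep(G, 2, s, "*")

  pr <- if (is.null(ipm$p_repro)) rep(1, n) else
    evaluate_predictor(ipm$p_repro, z, dv)
  off <- if (is.null(ipm$offspring)) rep(1, n) else
    evaluate_predictor(ipm$offspring, z, dv)
  if (any(names(ipm$recruit_mean$coefficients) %in% c("size", "size2")))
    stop("build_kernel: recruit_mean must not depend on size")
  rmu <- evaluate_predictor(ipm$recruit_mean, 0, dv)
  rd <- dnorm(z, rmu, ipm$recruit_sd) * h
  F_ <- outer(rd, pr * off)

  structure(list(P = P, F = F_, K = P + F_), class = "kernel_set")
}

#' Build a kernel sequence from an environmental driver matrix
#'
#' @param ipm An [env_ipm()].
#' @param env `T x d` matrix of driver values, one column per declared driver
#'   (matched by column name when present, by declaration order otherwise).
#' @param renormalize_growth Passed to [build_kernel()].
#' @return An object of class `kernel_sequence`: list with `K`, `P`, `F`
#'   (`n x n x T` arrays), `mesh`, and the environment matrix `env`.
#' @export
build_kernel_sequence <- function(ipm, env, renormalize_growth = FALSE) {
  stopifnot(inherits(ipm, "env_ipm"))
  env <- as.matrix(env)
  dn <- driver_names(ipm)
  if (ncol(env) != length(dn))
    stop("build_kernel_sequence: env has ", ncol(env),
         " columns but the model declares ", length(dn), " driver(s)")
  if (!is.null(colnames(env))) {
    if (!setequal(colnames(env), dn))
      stop("build_kernel_sequence: env columns do not match declared drivers")
    env <- env[, dn, drop = FALSE]
  } else {
    colnames(env) <- dn
  }
  T_ <- nrow(env)
  n <- ipm$mesh$n_mesh
  K <- array(0, c(n, n, T_))
  P <- array(0, c(n, n, T_))
  F_ <- array(0, c(n, n, T_))
  for (t in seq_len(T_)) {
    ks <- build_kernel(ipm, env[t, ], renormalize_growth = renormalize_growth)
    K[, , t] <- ks$K
    P[, , t] <- ks$P
    F_[, , t] <- ks$F
  }
  kernel_sequence(K, P, F_, mesh = ipm$mesh, env = env)
}

#' Construct a kernel sequence from arrays
#'
#' Low-level constructor used by [build_kernel_sequence()] and by tests that
#' assemble kernel timeseries directly.
#'
#' @param K `n x n x T` array of full kernels.
#' @param P,F Optional subkernel arrays with `K = P + F`; default `P = K`,
#'   `F = 0`.
#' @param mesh Optional [size_mesh()].
#' @param env Optional environment matrix that generated the sequence.
#' @return Object of class `kernel_sequence`.
#' @export
kernel_sequence <- function(K, P = NULL, F = NULL, mesh = NULL, env = NULL) {
  K <- as_kernel_array(K)
  if (is.null(P) && is.null(F)) {
    P <- K
    F <- array(0, dim(K))
  }
  P <- as_kernel_array(P)
  F <- as_kernel_array(F)
  if (!all(dim(P) == dim(K)) || !all(dim(F) == dim(K)))
    stop("kernel_sequence: P/F dimensions must match K")
  if (max(abs(P + F - K)) > 1e-12 * max(1, max(abs(K))))
    stop("kernel_sequence: K must equal P + F")
  structure(list(K = K, P = P, F = F, mesh = mesh, env = env),
            class = "kernel_sequence")
}

as_kernel_array <- function(x) {
  if (is.list(x)) {
    n <- nrow(x[[1]])
    a <- array(0, c(n, n, length(x)))
    for (t in seq_along(x)) a[, , t] <- x[[t]]
    return(a)
  }
  if (is.matrix(x)) return(array(x, c(dim(x), 1L)))
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x
}

#' @export
length.kernel_sequence <- function(x) dim(x$K)[3]

#' Timeseries of one kernel element
#'
#' @param seq A [kernel_sequence()].
#' @param i,j Row and column index.
#' @param which `"K"`, `"P"` or `"F"`.
#' @return Numeric vector `a_ij,t`, length `T`.
#' @export
element_series <- function(seq, i, j, which = "K") {
  stopifnot(inherits(seq, "kernel_sequence"))
  seq[[which]][i, j, ]
}

#' Arithmetic mean kernel of a sequence
#'
#' @param seq A [kernel_sequence()] or list/array of matrices.
#' @return The elementwise mean matrix; its dominant eigenvalue is the
#'   deterministic growth rate `lambda_1` of the mean environment.
#' @export
mean_kernel <- function(seq) {
  A <- if (inherits(seq, "kernel_sequence")) seq$K else as_kernel_array(seq)
  if (dim(A)[3] < 1L) stop("mean_kernel: empty sequence")
  rowMeans(A, dims = 2)
}

#' Dominant eigenvalue (spectral radius) of a nonnegative matrix
#'
#' Power iteration to relative tolerance 1e-10, falling back to a full
#' eigendecomposition when the iteration does not converge (e.g. reducible or
#' periodic matrices).
#'
#' @param M Square nonnegative matrix with finite entries.
#' @param tol Relative convergence tolerance.
#' @param max_iter Iteration cap before the eigendecomposition fallback.
#' @return The spectral radius `lambda_1`.
#' @export
dominant_eigenvalue <- function(M, tol = 1e-10, max_iter = 1000L) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("dominant_eigenvalue: non-finite entries")
  if (nrow(M) != ncol(M)) stop("dominant_eigenvalue: matrix must be square")
  n <- nrow(M)
  x <- rep(1 / n, n)
  lam <- NA_real_
  for (it in seq_len(max_iter)) {
    y <- as.vector(M %*% x)
    s <- sum(abs(y))
    if (s == 0) return(0)
    lam_new <- s / sum(abs(x))
    x <- y / s
    if (!is.na(lam) && abs(lam_new - lam) <= tol * max(1e-300, abs(lam_new))) {
      # one confirmation pass guards against slow oscillation
      y2 <- as.vector(M %*% x)
      lam2 <- sum(abs(y2))
      if (abs(lam2 - lam_new) <= 10 * tol * max(1e-300, abs(lam2)))
        return(lam_new)
    }
    lam <- lam_new
  }
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Dominant right eigenvector (stable structure), normalized to sum 1
#'
#' @param M Square nonnegative matrix.
#' @return Nonnegative vector summing to 1.
#' @export
stable_structure <- function(M) {
  e <- eigen(M)
  i <- which.max(Mod(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-8)) warning("stable_structure: eigenvector has mixed signs")
  pmax(v, 0) / sum(pmax(v, 0))
}
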