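#' Read an environmentally explicit IPM from a JSON model file
#'
#' The model file carries the mesh (`alpha`, `omega`, `n_mesh`), the driver
#' declarations (`name`, `mu`, `sigma2_init`) and the vital-rate regressions
#' (`survival`, `growth_mean`, `growth_sd`, `p_repro`, `offspring`,
#' `recruit_mean`, `recruit_sd`), each regression as
#' `{link, intercept, coefficients: {variable: value, ...}}` with
#' coefficients keyed by variable name (`size`, `size2`, a driver name, or
#' `driver:size`). `p_repro` and `offspring` may be omitted (identity value
#' 1); `recruit_mean` may be a plain number. This generic encoding can
#' transcribe published vital-rate regressions (e.g. database entries or
#' supplementary tables) without parsing their native formats.
#'
#' @param path JSON file path.
#' @return An [env_ipm()].
#' @seealso [write_model()], [validate_model()]
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("mesh", "drivers", "vital_rates"))
    if (is.null(doc[[f]])) stop("read_model: missing field '", f, "'")
  mesh <- size_mesh(doc$mesh$alpha, doc$mesh$omega, doc$mesh$n_mesh)
  drivers <- do.call(rbind, lapply(doc$drivers, function(d)
    data.frame(name = d$name, mu = d$mu, sigma2_init = d$sigma2_init,
               stringsAsFactors = FALSE)))
  if (is.null(drivers))
    drivers <- data.frame(name = character(0), mu = numeric(0),
                          sigma2_init = numeric(0))
  vr <- doc$vital_rates
  spec_from_json <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.numeric(x) && length(x) == 1L)
      return(linear_predictor(x, link = "identity"))
    linear_predictor(x$intercept, unlist(x$coefficients),
                     link = if (is.null(x$link)) "identity" else x$link)
  }
  env_ipm(
    mesh = mesh,
    survival = spec_from_json(vr$survival),
    growth_mean = spec_from_json(vr$growth_mean),
    growth_sd = vr$growth_sd,
    p_repro = spec_from_json(vr$p_repro),
    offspring = spec_from_json(vr$offspring),
    recruit_mean = spec_from_json(vr$recruit_mean),
    recruit_sd = vr$recruit_sd,
    drivers = drivers,
    name = if (is.null(doc$name)) "unnamed" else doc$name
  )
}

#' Write an IPM to the JSON model format
#'
#' Inverse of [read_model()]: the write-read round trip reproduces the model
#' exactly.
#'
#' @param ipm An [env_ipm()].
#' @param path Output JSON file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(ipm, path) {
  stopifnot(inherits(ipm, "env_ipm"))
  spec_to_json <- function(s) {
    if (is.null(s)) return(NULL)
    list(link = s$link, intercept = s$intercept,
         coefficients = as.list(s$coefficients))
  }
  doc <- list(
    name = ipm$name,
    mesh = list(alpha = ipm$mesh$alpha, omega = ipm$mesh$omega,
                n_mesh = ipm$mesh$n_mesh),
    drivers = lapply(seq_len(nrow(ipm$drivers)), function(i)
      list(name = ipm$drivers$name[i], mu = ipm$drivers$mu[i],
           sigma2_init = ipm$drivers$sigma2_init[i])),
    vital_rates = Filter(Negate(is.null), list(
      survival = spec_to_json(ipm$survival),
      growth_mean = spec_to_json(ipm$growth_mean),
      growth_sd = ipm$growth_sd,
      p_repro = spec_to_json(ipm$p_repro),
      offspring = spec_to_json(ipm$offspring),
      recruit_mean = spec_to_json(ipm$recruit_mean),
      recruit_sd = ipm$recruit_sd
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a species manifest
#'
#' A manifest records what a transcribed model is expected to look like:
#' species name, source citation, the driver list (names, optionally with
#' long-run means and baseline variances), and the expected long-run growth
#' regime (`">1"` or `"<1"`).
#'
#' @param path Manifest JSON path.
#' @return List of class `model_manifest`.
#' @export
read_manifest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("species", "drivers"))
    if (is.null(doc[[f]])) stop("read_manifest: missing field '", f, "'")
  structure(doc, class = "model_manifest")
}

#' Validate a model against its manifest
#'
#' Checks the declared drivers against the manifest (count and names), and
#' runs a baseline stochastic simulation (autocorrelation 0, proportional
#' variance 1) to report whether the estimated stochastic growth rate falls
#' on the manifest's side of 1. The growth-rate value itself is reported,
#' not asserted, since it is a stochastic estimate.
#'
#' @param ipm An [env_ipm()].
#' @param manifest A [read_manifest()] result (or equivalent list).
#' @param T Baseline simulation length (default 500).
#' @param burn_in Burn-in (default 200).
#' @param seed Baseline simulation seed.
#' @return List of class `validation_report`: `pass` (driver checks),
#'   `missing_drivers`, `extra_drivers`, `lambda_s`, `lambda_1`,
#'   `regime_expected`, `regime_observed`, `regime_match`.
#' @export
validate_model <- function(ipm, manifest, T = 500, burn_in = 200, seed = 1L) {
  stopifnot(inherits(ipm, "env_ipm"))
  want <- vapply(manifest$drivers, function(d) d$name, character(1))
  have <- driver_names(ipm)
  missing_drivers <- setdiff(want, have)
  extra_drivers <- setdiff(have, want)
  pass <- length(missing_drivers) == 0 && length(extra_drivers) == 0

  env <- generate_driver_matrix(ipm, phi = 0, sigma2_prop = 1, T = T,
                                seed = seed)
  seq <- build_kernel_sequence(ipm, env)
  n0 <- with_seed(child_seed(seed, 1L), {x <- rexp(ipm$mesh$n_mesh); x / sum(x)})
  lambda_s <- stochastic_growth_rate(project(seq, n0), burn_in = burn_in)
  lambda_1 <- dominant_eigenvalue(mean_kernel(seq))

  regime_expected <- manifest$expected_lambda_regime
  regime_observed <- if (lambda_s > 1) ">1" else "<1"
  regime_match <- is.null(regime_expected) ||
    identical(regime_expected, regime_observed)
  if (!is.null(regime_expected) && !regime_match)
    warning("validate_model: expected lambda regime ", regime_expected,
            " but estimated lambda_s = ", signif(lambda_s, 4))
  structure(list(pass = pass, missing_drivers = missing_drivers,
                 extra_drivers = extra_drivers, lambda_s = lambda_s,
                 lambda_1 = lambda_1, regime_expected = regime_expected,
                 regime_observed = regime_observed,
                 regime_match = regime_match),
            class = "validation_report")
}
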