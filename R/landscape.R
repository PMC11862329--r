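#' Landscape grid configuration
#'
#' Defines the fully factorial environmental parameter space: autocorrelation
#' levels by proportional-variance levels, plus the simulation protocol
#' shared by every cell. Defaults follow the study conditions: a 15 x 15
#' grid spanning autocorrelation -0.8..0.8 and proportional variance
#' 0.9..1.1 (±10% around the published model), 1000-step kernel sequences
#' with a 200-step burn-in, variance perturbation `delta = 1e-5`, and 1000
#' random initial structures for the average size distribution.
#'
#' @param phi_levels Autocorrelation levels (`|phi| < 1`).
#' @param sigma2_prop_levels Proportional-variance levels (>= 0).
#' @param T Kernel-sequence length.
#' @param burn_in Discarded leading steps (< `T`).
#' @param delta Variance perturbation size (> 0).
#' @param n_inits_asd Random initial structures for the ASD.
#' @param master_seed Integer master seed for all randomness.
#' @param shared_noise Reuse one white-noise stream per driver across all
#'   cells (common random numbers; default `TRUE`)? When `FALSE` each cell
#'   draws independent noise from a cell-specific child seed.
#' @return Object of class `grid_config`.
#' @export
grid_config <- function(phi_levels = seq(-0.8, 0.8, length.out = 15),
                        sigma2_prop_levels = seq(0.9, 1.1, length.out = 15),
                        T = 1000, burn_in = 200, delta = 1e-5,
                        n_inits_asd = 1000, master_seed = 1L,
                        shared_noise = TRUE) {
  if (any(abs(phi_levels) >= 1)) stop("grid_config: |phi| must be < 1")
  if (any(sigma2_prop_levels < 0))
    stop("grid_config: sigma2_prop levels must be >= 0")
  if (burn_in >= T) stop("grid_config: burn_in must be < T")
  if (delta <= 0) stop("grid_config: delta must be > 0")
  structure(list(phi_levels = phi_levels,
                 sigma2_prop_levels = sigma2_prop_levels,
                 T = as.integer(T), burn_in = as.integer(burn_in),
                 delta = delta, n_inits_asd = as.integer(n_inits_asd),
                 master_seed = as.integer(master_seed),
                 shared_noise = isTRUE(shared_noise)),
            class = "grid_config")
}

landscape_columns <- c("phi", "sigma2_prop", "lambda_s", "lambda_1", "sum_E",
                       "sum_E_P", "sum_E_F", "pf_contribution",
                       "expected_buffering", "deviance", "mbs_normalized",
                       "mbs_literal", "seed")

# Seeds for the auxiliary random objects shared across a landscape.
n0_seed <- function(master_seed) child_seed(master_seed, 900001L)
asd_seed <- function(master_seed) child_seed(master_seed, 900002L)

# Single-cell computation shared by run_landscape() and direct use.
run_cell <- function(ipm, phi, sigma2_prop, T, burn_in, delta, n_inits_asd,
                     env_seed, n0, subkernels = TRUE, structure = TRUE,
                     asd_seed_val = 1L) {
  env <- generate_driver_matrix(ipm, phi, sigma2_prop, T, env_seed)
  seq <- build_kernel_sequence(ipm, env)
  el <- stochastic_elasticity_matrix(seq, n0, burn_in = burn_in, delta = delta)
  lambda_1 <- dominant_eigenvalue(mean_kernel(seq))
  profile <- stage_buffering_profile(el$E)
  out <- list(phi = phi, sigma2_prop = sigma2_prop,
              lambda_s = el$lambda_s, lambda_1 = lambda_1,
              sum_E = el$sum_E, sum_E_P = NA_real_, sum_E_F = NA_real_,
              pf_contribution = NA_real_, expected_buffering = NA_real_,
              deviance = NA_real_, mbs_normalized = NA_real_,
              mbs_literal = NA_real_, seed = env_seed)
  if (subkernels) {
    sk <- subkernel_elasticities(seq, n0, burn_in = burn_in, delta = delta)
    out$sum_E_P <- sk$sum_E_P
    out$sum_E_F <- sk$sum_E_F
    out$pf_contribution <- sk$pf_contribution
  }
  if (structure) {
    asd <- average_size_distribution(seq, n_inits = n_inits_asd,
                                     burn_in = burn_in, seed = asd_seed_val)
    out$expected_buffering <- expected_buffering_given_asd(profile, asd)
    out$mbs_normalized <- mean_buffered_size(profile, ipm$mesh, "normalized")
    out$mbs_literal <- mean_buffered_size(profile, ipm$mesh, "literal")
  }
  out
}

#' Run the fully factorial autocorrelation-by-variance landscape
#'
#' For every grid cell: generate the driver timeseries, build the kernel
#' sequence, compute the stochastic growth rate, the whole-kernel and
#' (optionally) subkernel elasticities of variance, the average size
#' distribution, the structure-weighted expected buffering and the mean
#' buffered size. After all cells, the scaled buffering deviance is filled
#' in across cells. Deterministic given `master_seed`.
#'
#' @param ipm An [env_ipm()].
#' @param grid A [grid_config()].
#' @param subkernels Compute P/F subkernel elasticities per cell (doubles
#'   the perturbation work)? Default `TRUE`.
#' @param structure Compute ASD-based structure metrics per cell? Default
#'   `TRUE`.
#' @param progress Print per-cell progress to stderr? Default `FALSE`.
#' @return Landscape table: data frame with one row per cell and columns
#'   `phi, sigma2_prop, lambda_s, lambda_1, sum_E, sum_E_P, sum_E_F,
#'   pf_contribution, expected_buffering, deviance, mbs_normalized,
#'   mbs_literal, seed`.
#' @export
run_landscape <- function(ipm, grid = grid_config(), subkernels = TRUE,
                          structure = TRUE, progress = FALSE) {
  stopifnot(inherits(ipm, "env_ipm"), inherits(grid, "grid_config"))
  cells <- expand.grid(phi = grid$phi_levels,
                       sigma2_prop = grid$sigma2_prop_levels,
                       KEEP.OUT.ATTRS = FALSE)
  n0 <- with_seed(n0_seed(grid$master_seed),
                  {x <- rexp(ipm$mesh$n_mesh); x / sum(x)})
  aseed <- asd_seed(grid$master_seed)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    env_seed <- if (grid$shared_noise) grid$master_seed
                else child_seed(grid$master_seed, i)
    if (progress)
      message(sprintf("cell %d/%d: phi = %.3f, sigma2_prop = %.3f",
                      i, nrow(cells), cells$phi[i], cells$sigma2_prop[i]))
    rows[[i]] <- tryCatch(
      run_cell(ipm, cells$phi[i], cells$sigma2_prop[i], grid$T, grid$burn_in,
               grid$delta, grid$n_inits_asd, env_seed, n0,
               subkernels = subkernels, structure = structure,
               asd_seed_val = aseed),
      error = function(e) stop("run_landscape: cell (phi = ", cells$phi[i],
                               ", sigma2_prop = ", cells$sigma2_prop[i],
                               ") failed: ", conditionMessage(e)))
  }
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (structure && nrow(tab) >= 3L &&
      sd(tab$expected_buffering) > 0 && sd(tab$sum_E) > 0) {
    tab$deviance <- scaled_deviance(tab$expected_buffering, tab$sum_E)
  }
  tab[landscape_columns]
}

#' Write a landscape table to CSV at full floating precision
#'
#' @param table Landscape table from [run_landscape()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(table, path) {
  missing <- setdiff(landscape_columns, names(table))
  if (length(missing) > 0)
    stop("write_landscape: missing column(s): ",
         paste(missing, collapse = ", "))
  out <- table[landscape_columns]
  fmt <- as.data.frame(lapply(out, function(x)
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)),
    stringsAsFactors = FALSE)
  names(fmt) <- landscape_columns
  write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a landscape table written by [write_landscape()]
#'
#' @param path CSV file path.
#' @return Landscape table data frame.
#' @export
read_landscape <- function(path) {
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop("read_landscape: parse error in '", path, "': ",
                         conditionMessage(e)))
  missing <- setdiff(landscape_columns, names(tab))
  if (length(missing) > 0)
    stop("read_landscape: missing column(s) in '", path, "': ",
         paste(missing, collapse = ", "))
  for (cl in landscape_columns) tab[[cl]] <- as.numeric(tab[[cl]])
  tab[landscape_columns]
}
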