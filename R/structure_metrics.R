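#' Expected buffering given the average size distribution
#'
#' The per-stage buffering profile averaged under the population's average
#' size distribution: `sum_j asd_j * profile_j`. Comparing this
#' structure-weighted value with the raw `sum_E` across a landscape isolates
#' the contribution of population structure to buffering.
#'
#' @param profile Per-stage buffering values ([stage_buffering_profile()]).
#' @param asd Average size distribution (nonnegative, sums to 1).
#' @return Scalar expected buffering value.
#' @export
expected_buffering_given_asd <- function(profile, asd) {
  if (length(profile) != length(asd))
    stop("expected_buffering_given_asd: length mismatch")
  sum(asd * profile)
}

#' Scaled deviance between expected and raw buffering across a landscape
#'
#' Z-scores each vector across grid cells (mean 0, sample SD 1 with the
#' `n - 1` denominator) and returns their elementwise difference. Deviations
#' from 0 flag cells where population structure pushes buffering away from
#' what the demographic rates alone imply; the output has mean 0 by
#' construction.
#'
#' @param expected Vector of structure-weighted buffering values, one per
#'   grid cell.
#' @param sum_E Vector of summed elasticities of variance, same cells.
#' @return Vector of per-cell scaled deviances.
#' @export
scaled_deviance <- function(expected, sum_E) {
  if (length(expected) != length(sum_E))
    stop("scaled_deviance: length mismatch")
  if (length(expected) < 3L)
    stop("scaled_deviance: need at least 3 grid cells")
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0)
      stop("scaled_deviance: constant input vector (z-score undefined)")
    (x - mean(x)) / s
  }
  zscore(expected) - zscore(sum_E)
}

#' Mean buffered size
#'
#' The elasticity-weighted centroid of size: where across the size domain the
#' population's demographic buffering is concentrated. Weights are the
#' per-stage profile normalized by its sum; the centroid
#' `c = sum_j z_j * w_j` over mesh midpoints is expressed relative to the
#' size domain. The default `"normalized"` convention returns
#' `(c - alpha) / (omega - alpha)` (0 = smallest possible size, 1 = largest);
#' the `"literal"` convention returns `(c - alpha) / omega`. With
#' `alpha = 0` the two coincide.
#'
#' @param profile Per-stage buffering values.
#' @param mesh A [size_mesh()].
#' @param convention `"normalized"` (default) or `"literal"`.
#' @return Mean buffered size (scalar). With nonnegative (or nonpositive)
#'   weights the normalized value lies in `[0, 1]`; mixed-sign profiles may
#'   exit that interval, which triggers a warning rather than an error.
#' @export
mean_buffered_size <- function(profile, mesh,
                               convention = c("normalized", "literal")) {
  convention <- match.arg(convention)
  stopifnot(inherits(mesh, "size_mesh"))
  if (length(profile) != mesh$n_mesh)
    stop("mean_buffered_size: profile length must equal n_mesh")
  tot <- sum(profile)
  if (tot == 0)
    stop("mean_buffered_size: profile sums to 0 (centroid undefined)")
  w <- profile / tot
  centroid <- sum(mesh$midpoints * w)
  mbs <- if (convention == "normalized")
    (centroid - mesh$alpha) / (mesh$omega - mesh$alpha)
  else
    (centroid - mesh$alpha) / mesh$omega
  if (convention == "normalized" && (mbs < 0 || mbs > 1))
    warning("mean_buffered_size: mixed-sign profile pushed MBS outside [0, 1]")
  mbs
}
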