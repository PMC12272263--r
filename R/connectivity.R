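#' Extract a field-thresholded weighted seed region
#'
#' The seed region for one coil configuration is the set of vertices whose
#' field magnitude strictly exceeds `fraction` of the map maximum (default
#' the >50%-of-maximum rule). Each seed vertex gets a weight proportional
#' to its field value; with `normalize = "sum"` (default) the weights sum
#' to one, so the seed time series is a convex combination (a weighted
#' average); `normalize = "max"` divides by the maximum instead.
#'
#' @param field An `efield_map` or numeric per-vertex field vector.
#' @param fraction Threshold as fraction of maximum (default 0.5).
#' @param normalize `"sum"` or `"max"`.
#' @return List of class `seed_region` with `indices` (1-based) and
#'   `weights`.
#' @examples
#' extract_seed(c(1.0, 0.6, 0.4))  # vertices 1-2, weights 0.625 / 0.375
#' @export
extract_seed <- function(field, fraction = 0.5, normalize = c("sum", "max")) {
  normalize <- match.arg(normalize)
  f <- as.numeric(field)
  mx <- max(f)
  if (!is.finite(mx) || mx <= 0)
    stop_input("field has no positive values (degenerate)")
  idx <- which(f > fraction * mx)
  w <- f[idx]
  w <- if (normalize == "sum") w / sum(w) else w / max(w)
  structure(list(indices = idx, weights = w), class = "seed_region")
}

#' Weighted-average seed time series
#'
#' Sums the per-vertex time series over the seed, each multiplied by its
#' node weight: `s(t) = sum_v w_v x_v(t)`.
#'
#' @param seed A [extract_seed()] result.
#' @param ts A [time_series_matrix()].
#' @return Numeric vector of length `ncol(ts)`.
#' @export
weighted_timeseries <- function(seed, ts) {
  stopifnot(inherits(seed, "seed_region"))
  if (any(seed$indices < 1) || any(seed$indices > nrow(ts)))
    stop_input("seed vertex index out of range for the time-series matrix")
  drop(seed$weights %*% unclass(ts)[seed$indices, , drop = FALSE])
}

#' Mean covariate over all configurations
#'
#' Element-wise arithmetic mean of the weighted seed series of every coil
#' configuration; used as the shared partial-correlation covariate to
#' remove the component common to all placements.
#'
#' @param all_seed_series List of equal-length numeric vectors.
#' @return Numeric vector of the same length.
#' @export
make_covariate <- function(all_seed_series) {
  if (length(all_seed_series) == 0) stop_input("empty series list")
  lens <- vapply(all_seed_series, length, 1L)
  if (length(unique(lens)) != 1) stop_input("series lengths differ")
  colMeans(do.call(rbind, all_seed_series))
}

#' Seed-to-cortex partial correlation map
#'
#' For every vertex, regresses the covariate (plus an intercept) out of
#' both the seed series and the vertex series by least squares, then
#' Pearson-correlates the residuals. Vertices whose residual variance
#' falls below 1e-12 are returned as `NA` (undefined) rather than 0, so
#' they cannot compete in top-percentile sparsification.
#'
#' @param seed_series Length-T numeric vector.
#' @param ts A [time_series_matrix()] (V x T).
#' @param covariate Length-T numeric vector.
#' @return Numeric vector of per-vertex partial correlations in
#'   \[-1, 1\] (`NA` where undefined), class `connectivity_map`.
#' @export
partial_corr_map <- function(seed_series, ts, covariate) {
  T <- ncol(ts)
  if (length(seed_series) != T) stop_input("seed series length mismatch")
  if (length(covariate) != T) stop_input("covariate length mismatch")
  if (T < 3) stop_input("need at least 3 timepoints")
  D <- cbind(1, as.numeric(covariate))
  Q <- qr(D)
  rs <- qr.resid(Q, as.numeric(seed_series))
  rv <- qr.resid(Q, t(unclass(ts)))          # T x V residuals
  ss_s <- sum(rs^2)
  ss_v <- colSums(rv^2)
  num <- drop(crossprod(rv, rs))
  r <- num / sqrt(ss_s * ss_v)
  undef <- ss_v / T < 1e-12
  if (ss_s / T < 1e-12) undef <- rep(TRUE, length(r))
  r[undef] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  structure(r, class = "connectivity_map")
}
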