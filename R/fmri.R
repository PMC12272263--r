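#' Time-series matrix container
#'
#' @param data V x T numeric matrix (vertices in rows, timepoints in
#'   columns), arbitrary BOLD-like units.
#' @param TR Repetition time in seconds.
#' @return Matrix of class `time_series_matrix` with attribute `TR`.
#' @export
time_series_matrix <- function(data, TR) {
  data <- as.matrix(data)
  if (!is.numeric(TR) || length(TR) != 1 || TR <= 0)
    stop_input("'TR' must be a single positive number (seconds)")
  if (any(!is.finite(data))) stop_input("time series contains non-finite values")
  structure(data, TR = TR, class = c("time_series_matrix", "matrix", "array"))
}

#' Network signal model for synthetic resting-state data
#'
#' Generative stand-in for preprocessed resting-state fMRI: one latent
#' AR(1) series per network with unit stationary variance, plus i.i.d.
#' Gaussian vertex noise. A vertex in network n observes
#' `a_n * g_n(t) + sigma * eps(t)`, so the population correlation of two
#' same-network vertices is `a_n^2 / (a_n^2 + sigma^2)` and the expected
#' cross-network correlation is zero.
#'
#' @param amplitudes Length-7 vector of per-network latent amplitudes `a_n`
#'   (recycled from length 1).
#' @param sigma Vertex noise standard deviation.
#' @param rho AR(1) coefficient of the latents, in \[0, 1).
#' @param bandpass Logical; apply [band_pass()] after generation.
#' @param band Length-2 pass band in Hz (default 0.01-0.1, the standard
#'   resting-state band).
#' @return Object of class `network_signal_model`.
#' @export
network_signal_model <- function(amplitudes = 2, sigma = 1, rho = 0.3,
                                 bandpass = FALSE, band = c(0.01, 0.1)) {
  amplitudes <- rep_len(as.numeric(amplitudes), 7L)
  if (any(amplitudes < 0) || all(amplitudes == 0))
    stop_input("amplitudes must be >= 0 with at least one > 0")
  if (sigma < 0) stop_input("'sigma' must be >= 0")
  if (rho < 0 || rho >= 1) stop_input("'rho' must be in [0, 1)")
  structure(list(amplitudes = amplitudes, sigma = sigma, rho = rho,
                 bandpass = isTRUE(bandpass), band = band),
            class = "network_signal_model")
}

#' Simulate resting-state fMRI with planted network covariance
#'
#' Draws one latent AR(1) series per network (unit stationary variance;
#' innovations scaled by `sqrt(1 - rho^2)`), then assigns
#' `x_v(t) = a_n g_n(t) + sigma eps_v(t)` to every vertex v of network n.
#' Unassigned (label-0) vertices receive pure noise. Generation is a pure
#' function of (parcellation, model, n_timepoints, TR, seed).
#'
#' @param parcellation A `parcellation_map` (see [make_parcellation()]).
#' @param model A [network_signal_model()].
#' @param n_timepoints Number of timepoints (>= 10). Defaults emulating the
#'   source acquisitions: 1200 at TR 0.72 s for human-like runs.
#' @param TR Repetition time in seconds.
#' @param seed Integer random seed.
#' @return A [time_series_matrix()].
#' @export
simulate_rfmri <- function(parcellation, model, n_timepoints = 1200L,
                           TR = 0.72, seed = 1L) {
  stopifnot(inherits(model, "network_signal_model"))
  labels <- as.integer(unclass(parcellation))
  if (n_timepoints < 10) stop_input("'n_timepoints' must be >= 10")
  V <- length(labels)
  T <- as.integer(n_timepoints)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  rho <- model$rho
  lat <- matrix(stats::rnorm(7L * T), 7L, T)
  if (rho > 0) {
    s <- sqrt(1 - rho^2)
    for (t in 2:T) lat[, t] <- rho * lat[, t - 1] + s * lat[, t]
  }
  x <- matrix(0, V, T)
  if (model$sigma > 0) x[] <- stats::rnorm(V * T, sd = model$sigma)
  for (n in 1:7) {
    vs <- which(labels == n)
    if (length(vs) && model$amplitudes[n] > 0)
      x[vs, ] <- x[vs, ] + model$amplitudes[n] *
        matrix(lat[n, ], length(vs), T, byrow = TRUE)
  }
  ts <- time_series_matrix(x, TR)
  if (model$bandpass) ts <- band_pass(ts, model$band[1], model$band[2])
  ts
}

#' Band-pass filter a time-series matrix
#'
#' Zeroes spectral content outside `[low, high]` Hz by forward/inverse
#' discrete Fourier transform per vertex. The DC component is always
#' removed when `low > 0`, so filtered series have (numerically) zero mean.
#'
#' @param ts A [time_series_matrix()].
#' @param low,high Pass band edges in Hz; requires
#'   `0 <= low < high < 1 / (2 TR)` (Nyquist).
#' @return A filtered [time_series_matrix()].
#' @export
band_pass <- function(ts, low = 0.01, high = 0.1) {
  stopifnot(inherits(ts, "time_series_matrix"))
  TR <- attr(ts, "TR")
  nyq <- 1 / (2 * TR)
  if (low < 0 || low >= high) stop_input("need 0 <= low < high")
  if (high >= nyq)
    stop_input("'high' must be below the Nyquist frequency ", signif(nyq, 4),
               " Hz")
  T <- ncol(ts)
  freqs <- (seq_len(T) - 1) / (T * TR)
  freqs <- pmin(freqs, 1 / TR - freqs)   # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  sp <- stats::mvfft(t(unclass(ts)))
  sp[!keep, ] <- 0
  out <- t(Re(stats::mvfft(sp, inverse = TRUE))) / T
  time_series_matrix(out, TR)
}
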