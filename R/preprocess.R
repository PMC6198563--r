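# Conditioning of raw EMG ahead of spectral analysis and envelope metrics.
# Fixed pipeline order: band-pass (optional for simulated data) -> full-wave
# rectification -> unit-variance normalisation; each applied step is recorded
# in the `provenance` attribute of the conditioned signal.

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass. Zero-phase filtering
#' avoids the phase distortion that would bias downstream cumulant-density
#' lags. The upper edge is capped at 0.45 * fs.
#'
#' @param x Numeric signal.
#' @param lo_hz,hi_hz Band edges in Hz, `0 < lo_hz < hi_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order per pass (default 2).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, lo_hz, hi_hz, fs, order = 2) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  hi_hz <- min(hi_hz, 0.45 * fs)
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2)) {
    stop("band edges must satisfy 0 < lo < hi < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Full-wave rectification
#'
#' Elementwise absolute value. Rectification recovers motor-unit firing
#' timing information from interference EMG while discarding waveform shape.
#'
#' @param x Numeric signal.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(as.numeric(x))

#' Normalise a signal to zero mean and unit variance
#'
#' Uses the population (1/N) variance convention, so the realisation itself
#' has variance exactly 1. Returns a `conditioned_signal` whose `provenance`
#' attribute lists the applied steps.
#'
#' @param x Numeric signal with positive sample variance.
#' @param fs Sampling rate in Hz.
#' @param provenance Character vector of steps already applied to `x`.
#' @return A `conditioned_signal`: numeric vector with attributes `fs` and
#'   `provenance`.
#' @export
normalize_unit_variance <- function(x, fs = NA_real_, provenance = character()) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2L) stop("signal too short to normalise", call. = FALSE)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  if (v <= 0) stop("degenerate signal: zero variance", call. = FALSE)
  out <- (x - mu) / sqrt(v)
  structure(out, fs = fs, provenance = c(provenance, "normalize"),
            class = "conditioned_signal")
}

#' Moving-average envelope smoothing
#'
#' Centred moving average of a rectified signal; near the edges the window
#' shrinks so the output has the same length as the input. The 50 ms default
#' is the conventional envelope window for cocontraction analysis.
#'
#' @param x Rectified numeric signal.
#' @param window_ms Window length in milliseconds.
#' @param fs Sampling rate in Hz.
#' @return Smoothed signal, same length as `x`.
#' @export
smooth_envelope <- function(x, window_ms = 50, fs = 2000) {
  stopifnot_scalar(window_ms, "window_ms", positive = TRUE)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  x <- as.numeric(x)
  w <- max(1L, round(window_ms / 1000 * fs))
  if (w > length(x)) stop("smoothing window longer than signal", call. = FALSE)
  # cumulative-sum moving mean with shrinking edge windows
  half <- (w - 1) / 2
  n <- length(x)
  idx <- seq_len(n)
  lo <- pmax(1, ceiling(idx - half))
  hi <- pmin(n, floor(idx + half + if (w %% 2 == 0) 1 else 0))
  cs <- c(0, cumsum(x))
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Condition an EMG channel for coherence analysis
#'
#' Applies the fixed pipeline band-pass (optional) -> rectify -> normalise and
#' records provenance. Simulated data are already band-limited at source, so
#' the filter stage can be skipped.
#'
#' @param x Numeric signal (one EMG channel, millivolts).
#' @param fs Sampling rate in Hz.
#' @param band Band-pass edges in Hz, or `NULL` to skip filtering.
#' @return A `conditioned_signal`.
#' @export
condition_emg <- function(x, fs, band = c(5, 1000)) {
  steps <- character()
  x <- as.numeric(x)
  if (!is.null(band)) {
    x <- bandpass(x, band[1], band[2], fs)
    steps <- c(steps, sprintf("bandpass(%g-%g Hz)", band[1], min(band[2], 0.45 * fs)))
  }
  x <- rectify(x)
  steps <- c(steps, "rectify")
  normalize_unit_variance(x, fs = fs, provenance = steps)
}

#' @export
print.conditioned_signal <- function(x, ...) {
  cat(sprintf("<conditioned_signal> %d samples at %g Hz; steps: %s\n",
              length(x), attr(x, "fs"),
              paste(attr(x, "provenance"), collapse = " -> ")))
  invisible(x)
}
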