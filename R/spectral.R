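# Disjoint-segment spectral estimation for a pair of conditioned EMG signals:
# autospectra, cross-spectrum, coherence, phase, cumulant density and
# independence-null confidence limits, plus the cross-talk QC rule.
#
# Estimator class: L disjoint, non-overlapping, untapered segments of
# T = fs / resolution samples; per-segment periodograms averaged.  This is
# the class for which the upper 95% coherence confidence limit
# 1 - alpha^(1/(L-1)) is exact under independence.
#
# Scaling convention: f_ab(k) = (1/(L*T^2)) * sum_l conj(A_l(k)) * B_l(k),
# so that the sum of f_xx over the full (two-sided) frequency axis equals the
# segment-mean signal power (discrete Parseval).  The conj(X)*Y orientation
# makes a *positive* cumulant lag mean "y lags x", and gives phase slope
# -2*pi*delay for y a delayed copy of x.

#' Disjoint-segment spectra, coherence and phase for a signal pair
#'
#' Splits both signals into `L` disjoint segments of `fs / resolution_hz`
#' samples (any trailing partial segment is discarded), demeans each segment,
#' and averages per-segment periodograms and cross-periodograms. Coherence is
#' `|f_xy|^2 / (f_xx * f_yy)` and the upper confidence limit under the
#' independence null is `1 - alpha^(1/(L-1))`.
#'
#' @param x,y Numeric signals of equal length (typically
#'   [condition_emg()] output), or `conditioned_signal` objects.
#' @param fs Sampling rate in Hz; taken from `x` when it carries one.
#' @param resolution_hz Frequency resolution in Hz; segment length is
#'   `fs / resolution_hz` samples and must be an integer. Default 1 Hz.
#' @param alpha Significance level for the confidence limit (default 0.05).
#' @return A `spectral_estimate` with one-sided fields `freqs`, `f_xx`,
#'   `f_yy`, `f_xy` (complex), `coherence`, `phase`, plus `L`, `T`, `fs`,
#'   `coh_cl`, and the full-axis spectra in `$full` (used by the cumulant).
#' @references Frequency-domain framework for point-process/time-series
#'   association analysis with disjoint-segment estimators.
#' @export
estimate_spectra <- function(x, y, fs = NULL, resolution_hz = 1, alpha = 0.05) {
  fsx <- attr(x, "fs"); fsy <- attr(y, "fs")
  if (is.null(fs)) fs <- fsx
  if (is.null(fs) || is.na(fs)) stop("`fs` must be supplied", call. = FALSE)
  if (!is.null(fsx) && !is.na(fsx) && !is.null(fsy) && !is.na(fsy) &&
      abs(fsx - fsy) > 1e-9) {
    stop("x and y have mismatched sampling rates", call. = FALSE)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  stopifnot_scalar(resolution_hz, "resolution_hz", positive = TRUE)
  Tseg <- fs / resolution_hz
  if (abs(Tseg - round(Tseg)) > 1e-9) {
    stop("`resolution_hz` must divide fs into an integer segment length",
         call. = FALSE)
  }
  Tseg <- as.integer(round(Tseg))
  L <- length(x) %/% Tseg
  if (L < 2L) stop("insufficient data: need at least 2 complete segments",
                   call. = FALSE)

  xs <- matrix(x[seq_len(L * Tseg)], nrow = Tseg)
  ys <- matrix(y[seq_len(L * Tseg)], nrow = Tseg)
  # demean each segment: only alters the DC bin exactly, but recorded anyway
  xs <- sweep(xs, 2, colMeans(xs))
  ys <- sweep(ys, 2, colMeans(ys))
  X <- stats::mvfft(xs)
  Y <- stats::mvfft(ys)
  # demeaning zeroes the DC coefficient exactly; clear the rounding residue
  X[1, ] <- 0
  Y[1, ] <- 0

  scale <- 1 / (L * Tseg^2)
  f_xx_full <- rowSums(Mod(X)^2) * scale
  f_yy_full <- rowSums(Mod(Y)^2) * scale
  f_xy_full <- rowSums(Conj(X) * Y) * scale

  nf <- Tseg %/% 2L + 1L  # bins 0 .. Nyquist (Tseg even) or 0 .. (T-1)/2
  freqs <- (seq_len(nf) - 1) * resolution_hz
  f_xx <- f_xx_full[seq_len(nf)]
  f_yy <- f_yy_full[seq_len(nf)]
  f_xy <- f_xy_full[seq_len(nf)]
  denom <- f_xx * f_yy
  coh <- ifelse(denom > 0, Mod(f_xy)^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  structure(
    list(freqs = freqs, f_xx = f_xx, f_yy = f_yy, f_xy = f_xy,
         coherence = coh, phase = Arg(f_xy),
         L = L, T = Tseg, fs = fs, alpha = alpha,
         coh_cl = 1 - alpha^(1 / (L - 1)),
         full = list(f_xx = f_xx_full, f_yy = f_yy_full, f_xy = f_xy_full)),
    class = "spectral_estimate")
}

#' @export
print.spectral_estimate <- function(x, ...) {
  sig <- sum(x$coherence[x$freqs >= 1 & x$freqs <= 60] > x$coh_cl)
  cat(sprintf(
    "<spectral_estimate> L=%d segments of T=%d samples (%g Hz resolution)\n",
    x$L, x$T, x$fs / x$T))
  cat(sprintf("  95%% coherence limit %.4f; %d of 1-60 Hz bins above it\n",
              x$coh_cl, sig))
  invisible(x)
}

# Rebuild the full Hermitian cross-spectrum from a one-sided vector.
hermitian_full <- function(one_sided, Tseg) {
  full <- complex(Tseg)
  nf <- length(one_sided)
  full[seq_len(nf)] <- one_sided
  if (Tseg %% 2 == 0) {
    # bins 1..T/2-1 mirror into T-1..T/2+1 (1-based: indices 2..T/2)
    if (nf > 2) full[Tseg:(Tseg %/% 2 + 2)] <- Conj(one_sided[2:(nf - 1)])
  } else {
    if (nf > 1) full[Tseg:(Tseg %/% 2 + 2)] <- Conj(one_sided[2:nf])
  }
  full
}

# Shared inverse-transform core for individual and pooled cumulants.
# cross_full: full-axis cross-spectral (or coherency) vector; var_q: lag-
# constant variance of the estimate under the independence null.
cumulant_from_cross <- function(cross_full, fs, max_lag_s, var_q, alpha = 0.05) {
  Tseg <- length(cross_full)
  q_all <- Re(stats::fft(cross_full, inverse = TRUE))  # q(j) = sum_k f(k) e^{+i 2 pi k j / T}
  m <- min(floor(max_lag_s * fs), (Tseg - 1L) %/% 2L)
  j <- -m:m
  q <- q_all[ifelse(j >= 0, j + 1L, Tseg + j + 1L)]
  z <- stats::qnorm(1 - alpha / 2)
  cl <- z * sqrt(var_q)
  structure(
    list(lags = j / fs, q = q, cl_upper = cl, cl_lower = -cl,
         var_q = var_q, fs = fs),
    class = "cumulant_density")
}

#' Cumulant density from a spectral estimate
#'
#' Inverse discrete Fourier transform of the estimated cross-spectrum over the
#' full frequency axis, restricted to lags within `+/- max_lag_s` (default
#' 250 ms). The flat 95% confidence band is `+/- 1.96 * sqrt(Var)` with the
#' lag-constant independence-null variance
#' `Var = sum_k f_xx(k) f_yy(k) / L` over the full axis.
#'
#' A positive peak at positive lag means activity in `y` lags activity in `x`.
#'
#' @param est A `spectral_estimate`.
#' @param max_lag_s Lag half-range in seconds (default 0.25).
#' @return A `cumulant_density` with fields `lags` (s), `q`, `cl_upper`,
#'   `cl_lower`.
#' @export
cumulant_density <- function(est, max_lag_s = 0.25) {
  stopifnot(inherits(est, "spectral_estimate"))
  var_q <- sum(est$full$f_xx * est$full$f_yy) / est$L
  cumulant_from_cross(est$full$f_xy, est$fs, max_lag_s, var_q, est$alpha)
}

#' @export
print.cumulant_density <- function(x, ...) {
  pk <- cumulant_peak(x)
  cat(sprintf(
    "<cumulant_density> lags %+.0f..%+.0f ms; peak q=%.4g at %+.1f ms (95%% band +/-%.4g)\n",
    1000 * min(x$lags), 1000 * max(x$lags), pk$q, 1000 * pk$lag, x$cl_upper))
  invisible(x)
}

# Location and height of the maximum of q; exact ties resolved toward the
# smallest |lag|.
cumulant_peak <- function(cum) {
  ord <- order(-cum$q, abs(cum$lags))
  i <- ord[1L]
  list(lag = cum$lags[i], q = cum$q[i])
}

#' Cross-talk quality control
#'
#' Electrode cross-talk mimics common drive as high coherence across a wide
#' frequency range combined with near-zero-lag synchronisation in the
#' cumulant density. A record pair is flagged when the fraction of 1--60 Hz
#' coherence bins above the confidence limit exceeds `broadband_threshold`
#' AND the cumulant peak both exceeds its upper confidence limit and sits
#' within `zero_lag_ms` of zero lag.
#'
#' @param est A `spectral_estimate`.
#' @param cum The matching `cumulant_density`.
#' @param broadband_threshold Fraction of 1--60 Hz bins above the coherence
#'   limit that counts as "broad band" (default 0.5).
#' @param zero_lag_ms Half-width of the "zero lag" window in ms (default 3).
#' @return A `crosstalk_report` with `broadband_fraction`, `zero_lag_peak`,
#'   `peak_lag_ms` and `flagged`.
#' @export
crosstalk_qc <- function(est, cum, broadband_threshold = 0.5, zero_lag_ms = 3) {
  stopifnot(inherits(est, "spectral_estimate"), inherits(cum, "cumulant_density"))
  sel <- est$freqs >= 1 & est$freqs <= 60
  broadband <- mean(est$coherence[sel] > est$coh_cl)
  pk <- cumulant_peak(cum)
  zero_lag <- (abs(pk$lag) * 1000 <= zero_lag_ms) && (pk$q > cum$cl_upper)
  structure(
    list(broadband_fraction = broadband,
         zero_lag_peak = zero_lag,
         peak_lag_ms = pk$lag * 1000,
         flagged = (broadband > broadband_threshold) && zero_lag),
    class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat(sprintf(
    "<crosstalk_report> broadband fraction %.2f; peak at %+.1f ms (zero-lag: %s) -> %s\n",
    x$broadband_fraction, x$peak_lag_ms,
    if (x$zero_lag_peak) "yes" else "no",
    if (x$flagged) "FLAGGED for cross-talk" else "clean"))
  invisible(x)
}
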