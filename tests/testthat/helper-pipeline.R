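# Shared helpers: run the standard conditioning + spectral stage on a
# simulated record, and build small constructed spectral estimates for
# pooling edge cases.

analyse_record <- function(rec, resolution_hz = 1) {
  x <- condition_emg(rec$samples[, 1], rec$fs, band = NULL)
  y <- condition_emg(rec$samples[, 2], rec$fs, band = NULL)
  estimate_spectra(x, y, resolution_hz = resolution_hz)
}

# Pair of unit-variance Gaussian signals sharing a fraction `rho` of a common
# source, giving true coherence rho^2 at every frequency.
gauss_pair <- function(n, rho, seed, fs = 2000) {
  set.seed(seed)
  s <- rnorm(n)
  x <- sqrt(rho) * s + sqrt(1 - rho) * rnorm(n)
  y <- sqrt(rho) * s + sqrt(1 - rho) * rnorm(n)
  list(x = normalize_unit_variance(x, fs = fs),
       y = normalize_unit_variance(y, fs = fs))
}

# Minimal hand-built spectral_estimate with flat unit autospectra and a
# chosen complex cross-spectrum (one-sided), for pooling arithmetic tests.
fake_estimate <- function(f_xy_onesided, L = 10, resolution_hz = 1) {
  nf <- length(f_xy_onesided)
  Tseg <- (nf - 1) * 2
  full <- c(f_xy_onesided, Conj(rev(f_xy_onesided[2:(nf - 1)])))
  structure(
    list(freqs = (seq_len(nf) - 1) * resolution_hz,
         f_xx = rep(1, nf), f_yy = rep(1, nf), f_xy = f_xy_onesided,
         coherence = pmin(Mod(f_xy_onesided)^2, 1),
         phase = Arg(f_xy_onesided),
         L = L, T = Tseg, fs = Tseg * resolution_hz, alpha = 0.05,
         coh_cl = 1 - 0.05^(1 / (L - 1)),
         full = list(f_xx = rep(1, Tseg), f_yy = rep(1, Tseg),
                     f_xy = full)),
    class = "spectral_estimate")
}
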