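# Synthetic inputs with the statistical structure the analyses assume:
# two-channel EMG driven by a shared band-limited oscillatory input to
# partially independent motor-unit pools, stimulus-locked H-reflex sweep sets
# with configurable suppression, and torque trials.
#
# All randomness flows from one integer seed: stream s of a simulation with
# master seed m uses split_seed(m, s), so every record, subject and unit has
# its own reproducible stream.

#' Configuration for the common-drive EMG simulator
#'
#' The two channels represent proximal and distal electrode sites over the
#' same muscle. Each channel has its own pool of motor units (no shared
#' units, mirroring electrode separation beyond muscle-fibre length); unit
#' `i` of channel `c` fires as an inhomogeneous point process with rate
#' `base_rate_hz * max(0, 1 + drive_gain * (kappa * s_c(t) +
#' (1 - kappa) * xi_ci(t)))`, where `s` is one shared band-limited Gaussian
#' drive (delayed per channel by `drive_delay_ms` to emulate conduction
#' delays) and the `xi` are independent band-limited noises. Spike trains are
#' convolved with a biphasic motor-unit action-potential kernel; channel 2 can
#' be contaminated by a fraction of channel 1 (`crosstalk_coeff`).
#'
#' @param fs Sampling rate, Hz (default 2000).
#' @param duration_s Record length, s (default 120, a two-minute static
#'   contraction).
#' @param n_units_per_channel Motor units per channel (default 40).
#' @param kappa Common-drive coupling in [0, 1] (default 0.4).
#' @param drive_bands Matrix with rows `(lo_hz, hi_hz, relative_power)`;
#'   default alpha 5-15 Hz (0.4) + beta 15-35 Hz (0.6).
#' @param base_rate_hz Mean motor-unit firing rate (default 10 Hz).
#' @param drive_gain Rate-modulation depth (default 0.5).
#' @param drive_delay_ms Per-channel conduction delay of the shared drive, ms
#'   (default `c(5, 12)`, so channel 2 lags channel 1 by 7 ms).
#' @param muap_duration_ms Action-potential kernel length (default 10 ms).
#' @param crosstalk_coeff Mixing fraction in [0, 1) added to channel 2
#'   (default 0).
#' @param noise_sd Additive Gaussian noise, mV (default 0.01).
#' @param seed Master seed.
#' @return A `drive_sim_config` list.
#' @export
drive_sim_config <- function(fs = 2000, duration_s = 120,
                             n_units_per_channel = 40, kappa = 0.4,
                             drive_bands = rbind(c(5, 15, 0.4),
                                                 c(15, 35, 0.6)),
                             base_rate_hz = 10, drive_gain = 0.5,
                             drive_delay_ms = c(5, 12),
                             muap_duration_ms = 10, crosstalk_coeff = 0,
                             noise_sd = 0.01, seed = 1L) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  if (abs(duration_s * fs - round(duration_s * fs)) > 1e-9) {
    stop("duration_s * fs must be an integer sample count", call. = FALSE)
  }
  if (kappa < 0 || kappa > 1) stop("`kappa` must lie in [0, 1]", call. = FALSE)
  if (crosstalk_coeff < 0 || crosstalk_coeff >= 1) {
    stop("`crosstalk_coeff` must lie in [0, 1)", call. = FALSE)
  }
  drive_bands <- matrix(as.numeric(drive_bands), ncol = 3)
  if (any(drive_bands[, 1] >= drive_bands[, 2]) || any(drive_bands[, 3] < 0)) {
    stop("drive bands must be (lo, hi, power >= 0) with lo < hi", call. = FALSE)
  }
  structure(
    list(fs = fs, duration_s = duration_s,
         n_units_per_channel = as.integer(n_units_per_channel), kappa = kappa,
         drive_bands = drive_bands, base_rate_hz = base_rate_hz,
         drive_gain = drive_gain, drive_delay_ms = as.numeric(drive_delay_ms),
         muap_duration_ms = muap_duration_ms,
         crosstalk_coeff = crosstalk_coeff, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "drive_sim_config")
}

# Band-limited unit-variance Gaussian noise: `n` samples at rate `fs`, power
# placed in the given bands, synthesised by FFT masking of white noise (FFT
# length padded to a composite size).  Each returned column has unit variance.
band_limited_noise <- function(n, fs, bands, n_series = 1L) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  w <- matrix(stats::rnorm(nfft * n_series), nrow = nfft)
  W <- stats::mvfft(w)
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  freqs <- pmin(freqs, fs - freqs)  # two-sided axis folded
  gain <- numeric(nfft)
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands[b, 1] & freqs <= bands[b, 2]
    gain[sel] <- sqrt(bands[b, 3])
  }
  z <- Re(stats::mvfft(W * gain, inverse = TRUE))[seq_len(n), , drop = FALSE] / nfft
  sds <- sqrt(colMeans(z^2))
  sds[sds == 0] <- 1
  sweep(z, 2, sds, "/")
}

# Inner (decimated) sampling rate for rate-modulation work: the drive bands
# live far below the EMG bandwidth, so rates are synthesised at >= 4x the top
# band edge and spike times recovered in continuous time.
inner_rate <- function(fs, bands) {
  top <- max(bands[, 2])
  decim <- max(1L, floor(fs / max(4 * top, 50)))
  list(fs = fs / decim, decim = decim)
}

# Fractional circular delay of a series by `d` samples via linear
# interpolation (adequate at >= 4x oversampling of the band of interest).
fractional_shift <- function(x, d) {
  n <- length(x)
  i <- (seq_len(n) - 1 - d) %% n
  i0 <- floor(i); w <- i - i0
  x[(i0 %% n) + 1L] * (1 - w) + x[((i0 + 1L) %% n) + 1L] * w
}

# Spike sample indices (at full rate fs, trace length n) for one unit with
# piecewise-linear integrated rate given at fs_inner.  Exact time-rescaling
# inversion: draw N ~ Poisson(total mass), place ordered uniform marks on the
# integrated-rate axis and invert to continuous spike times.
sample_spike_indices <- function(rate_inner, fs_inner, fs, n) {
  cum <- cumsum(rate_inner) / fs_inner
  total <- cum[length(cum)]
  if (total <= 0) return(integer(0))
  n_sp <- stats::rpois(1, total)
  if (n_sp == 0) return(integer(0))
  marks <- sort(stats::runif(n_sp, 0, total))
  bin <- findInterval(marks, cum) + 1L
  cum0 <- c(0, cum)
  slope <- rate_inner[bin]  # mass accrues at rate_inner[bin] within bin
  frac <- ifelse(slope > 0, (marks - cum0[bin]) / (slope / fs_inner), 0.5)
  t_sp <- (bin - 1 + pmin(pmax(frac, 0), 1)) / fs_inner
  idx <- floor(t_sp * fs) + 1L
  idx[idx >= 1L & idx <= n]
}

# Biphasic motor-unit action potential: first derivative of a Gaussian,
# peak amplitude 1, support = duration_ms.
muap_kernel <- function(fs, duration_ms = 10) {
  len <- max(3L, round(duration_ms / 1000 * fs))
  t <- seq_len(len) - (len + 1) / 2
  s <- len / 6
  k <- -t / s^2 * exp(-t^2 / (2 * s^2))
  k / max(abs(k))
}

#' Simulate a two-channel common-drive EMG record
#'
#' See [drive_sim_config()] for the generative model. The same configuration
#' and seed always produce the identical sample matrix.
#'
#' @param cfg A [drive_sim_config()].
#' @return An [emg_record()] with channels `TA_prox` and `TA_dist`.
#' @export
simulate_common_drive_emg <- function(cfg) {
  stopifnot(inherits(cfg, "drive_sim_config"))
  n <- round(cfg$duration_s * cfg$fs)
  nu <- cfg$n_units_per_channel
  kern <- muap_kernel(cfg$fs, cfg$muap_duration_ms)
  inner <- inner_rate(cfg$fs, cfg$drive_bands)
  n_inner <- ceiling(n / inner$decim) + 1L

  shared <- with_seed(split_seed(cfg$seed, 0L), {
    band_limited_noise(n_inner, inner$fs, cfg$drive_bands, 1L)[, 1]
  })

  channels <- matrix(0, nrow = n, ncol = 2)
  for (ch in 1:2) {
    d_inner <- cfg$drive_delay_ms[ch] / 1000 * inner$fs
    s_ch <- fractional_shift(shared, d_inner)
    channels[, ch] <- with_seed(split_seed(cfg$seed, ch), {
      xi <- band_limited_noise(n_inner, inner$fs, cfg$drive_bands, nu)
      amps <- stats::runif(nu, 0.5, 1.5)  # motor-unit size heterogeneity
      common <- cfg$kappa * s_ch
      idx_all <- vector("list", nu)
      for (i in seq_len(nu)) {
        rate <- cfg$base_rate_hz *
          pmax(0, 1 + cfg$drive_gain * (common + (1 - cfg$kappa) * xi[, i]))
        idx_all[[i]] <- sample_spike_indices(rate, inner$fs, cfg$fs, n)
      }
      spikes <- numeric(n)
      idx <- unlist(idx_all)
      if (length(idx) > 0) {
        w <- rep(amps, lengths(idx_all))
        acc <- rowsum(w, idx)
        spikes[as.integer(rownames(acc))] <- acc[, 1]
      }
      emg <- 0.1 * fft_convolve_same(spikes, kern)
      emg + stats::rnorm(n, sd = cfg$noise_sd)
    })
  }
  if (cfg$crosstalk_coeff > 0) {
    channels[, 2] <- channels[, 2] + cfg$crosstalk_coeff * channels[, 1]
  }
  emg_record(channels, fs = cfg$fs, channel_labels = c("TA_prox", "TA_dist"),
             subject_id = sprintf("sim%d", cfg$seed), group = "CON",
             state = "static")
}

# Linear convolution via FFT, trimmed to the input length and aligned so the
# kernel centre maps onto each spike time.
fft_convolve_same <- function(x, k) {
  n <- length(x); m <- length(k)
  nf <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nf - n))) *
                       stats::fft(c(k, numeric(nf - m))), inverse = TRUE)) / nf
  off <- (m - 1L) %/% 2L
  y[(1L + off):(n + off)]
}

#' Configuration for the H-reflex sweep simulator
#'
#' Emulates the stimulation control of a reflex experiment: every sweep
#' carries an M-wave whose amplitude is held near `m_target_pct` of M_max
#' (afferent-input control) and an H-reflex whose state-dependent mean is
#' `h_rest_mean_pct` at rest and `h_rest_mean_pct * (1 - suppression_fraction)`
#' at dorsiflexion onset. Subject-level means and trial-level amplitudes vary
#' as truncated Gaussians; waveforms are fixed biphasic templates scaled to
#' the drawn amplitudes plus additive baseline noise.
#'
#' @param n_subjects_per_group Subjects to simulate (default 15).
#' @param n_trials_per_state Stimulated sweeps per state (default 15).
#' @param m_target_pct Target M-wave amplitude, % of M_max (default 10).
#' @param m_sd_pct Trial-level SD of the M amplitude (default 1).
#' @param h_rest_mean_pct Population mean resting H-reflex, % of M_max
#'   (default 40).
#' @param h_rest_sd_pct Between-subject SD of the resting H-reflex
#'   (default 15).
#' @param suppression_fraction Fractional H-reflex reduction at onset
#'   (default 0.37; 0 means no suppression, negative means facilitation).
#' @param trial_noise_sd_pct Trial-level SD of the H amplitude (default 5).
#' @param waveform_noise_sd_mv Additive baseline noise per sample, mV
#'   (default 0.02).
#' @param m_max_mv Maximal M-response, mV (default 8).
#' @param fs Sampling rate (default 2000 Hz).
#' @param sweep_duration_s Sweep extent post-stimulus (default 0.08 s).
#' @param m_window,h_window Analysis windows, s post-stimulus.
#' @param seed Master seed.
#' @return An `hreflex_sim_config` list.
#' @export
hreflex_sim_config <- function(n_subjects_per_group = 15,
                               n_trials_per_state = 15,
                               m_target_pct = 10, m_sd_pct = 1,
                               h_rest_mean_pct = 40, h_rest_sd_pct = 15,
                               suppression_fraction = 0.37,
                               trial_noise_sd_pct = 5,
                               waveform_noise_sd_mv = 0.02,
                               m_max_mv = 8, fs = 2000,
                               sweep_duration_s = 0.08,
                               m_window = c(0.005, 0.025),
                               h_window = c(0.025, 0.055),
                               seed = 1L) {
  if (n_trials_per_state < 1L) stop("need at least 1 trial per state", call. = FALSE)
  for (s in c(m_sd_pct, h_rest_sd_pct, trial_noise_sd_pct, waveform_noise_sd_mv)) {
    if (s < 0) stop("standard deviations must be nonnegative", call. = FALSE)
  }
  if (suppression_fraction > 1) {
    stop("`suppression_fraction` cannot exceed 1", call. = FALSE)
  }
  structure(
    list(n_subjects_per_group = as.integer(n_subjects_per_group),
         n_trials_per_state = as.integer(n_trials_per_state),
         m_target_pct = m_target_pct, m_sd_pct = m_sd_pct,
         h_rest_mean_pct = h_rest_mean_pct, h_rest_sd_pct = h_rest_sd_pct,
         suppression_fraction = suppression_fraction,
         trial_noise_sd_pct = trial_noise_sd_pct,
         waveform_noise_sd_mv = waveform_noise_sd_mv,
         m_max_mv = m_max_mv, fs = fs, sweep_duration_s = sweep_duration_s,
         m_window = as.numeric(m_window), h_window = as.numeric(h_window),
         seed = as.integer(seed)),
    class = "hreflex_sim_config")
}

# Biphasic reflex template of unit peak-to-peak amplitude centred in `window`.
reflex_template <- function(n_samples, fs, window, width_frac = 0.5) {
  t <- (seq_len(n_samples) - 1) / fs
  centre <- mean(window)
  s <- diff(window) * width_frac / 6
  u <- (t - centre)
  k <- -u / s^2 * exp(-u^2 / (2 * s^2))
  k / (max(k) - min(k))
}

#' Simulate an H-reflex sweep dataset
#'
#' Generates, per subject and state, a [sweep_set()] of stimulus-locked
#' sweeps following the model in [hreflex_sim_config()].
#'
#' @param cfg An [hreflex_sim_config()].
#' @return List of `sweep_set` objects (one per subject and state, rest
#'   first), each tagged with its subject id.
#' @export
simulate_hreflex_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "hreflex_sim_config"))
  ns <- round(cfg$sweep_duration_s * cfg$fs)
  m_tpl <- reflex_template(ns, cfg$fs, cfg$m_window)
  h_tpl <- reflex_template(ns, cfg$fs, cfg$h_window)
  out <- list()
  for (subj in seq_len(cfg$n_subjects_per_group)) {
    h_rest_subj <- with_seed(split_seed(cfg$seed, 100L + subj), {
      max(1, stats::rnorm(1, cfg$h_rest_mean_pct, cfg$h_rest_sd_pct))
    })
    for (state in c("rest", "onset")) {
      h_mean <- if (state == "rest") h_rest_subj
                else h_rest_subj * (1 - cfg$suppression_fraction)
      stream <- 1000L * subj + (state == "onset")
      sweeps <- with_seed(split_seed(cfg$seed, stream), {
        nt <- cfg$n_trials_per_state
        m_amp <- pmax(0, stats::rnorm(nt, cfg$m_target_pct, cfg$m_sd_pct))
        h_amp <- pmax(0, stats::rnorm(nt, h_mean, cfg$trial_noise_sd_pct))
        sw <- matrix(stats::rnorm(nt * ns, sd = cfg$waveform_noise_sd_mv),
                     nrow = nt)
        mv <- cfg$m_max_mv / 100
        sw + outer(m_amp * mv, m_tpl) + outer(h_amp * mv, h_tpl)
      })
      out[[length(out) + 1L]] <- sweep_set(
        sweeps, fs = cfg$fs, state = state,
        m_window = cfg$m_window, h_window = cfg$h_window,
        m_max = cfg$m_max_mv, subject_id = sprintf("S%02d", subj))
    }
  }
  out
}

#' Simulate a dorsiflexion torque trial
#'
#' Sigmoidal rise from a silent baseline to `peak` along a smoothstep
#' profile `peak * (3u^2 - 2u^3)`, `u = (t - t_on)/T_r`, with the rise time
#' `T_r = 1.5 * peak / rise_rate` chosen so the maximal slope equals
#' `rise_rate` exactly. The trace is exactly zero before the onset at 1 s
#' (the returned `onset_index`), apart from an optional countermovement dip
#' and additive Gaussian noise.
#'
#' @param rise_rate Maximal rise slope, Nm/s.
#' @param peak Peak torque, Nm (> 0).
#' @param countermovement_depth Depth of the pre-onset dip, Nm (default 0).
#' @param fs Sampling rate (default 1000 Hz).
#' @param duration_s Trace length (default 4 s; rise starts after a 1 s
#'   baseline).
#' @param noise_sd Additive noise SD, Nm (default 0).
#' @param seed Seed for the noise stream.
#' @return A [torque_trial()].
#' @export
simulate_torque_trial <- function(rise_rate, peak, countermovement_depth = 0,
                                  fs = 1000, duration_s = 4, noise_sd = 0,
                                  seed = 1L) {
  stopifnot_scalar(peak, "peak", positive = TRUE)
  stopifnot_scalar(rise_rate, "rise_rate", positive = TRUE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  onset_s <- 1
  rise_s <- 1.5 * peak / rise_rate
  u <- pmin(pmax((t - onset_s) / rise_s, 0), 1)
  torque <- peak * (3 * u^2 - 2 * u^3)
  if (countermovement_depth > 0) {
    dip_centre <- onset_s - 0.15
    torque <- torque - countermovement_depth *
      exp(-(t - dip_centre)^2 / (2 * 0.05^2))
  }
  if (noise_sd > 0) {
    torque <- torque + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  }
  torque_trial(torque, fs = fs, onset_index = round(onset_s * fs) + 1L)
}
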