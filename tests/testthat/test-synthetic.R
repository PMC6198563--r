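test_that("the EMG simulator is deterministic given its seed", {
  cfg <- drive_sim_config(duration_s = 5, seed = 41)
  r1 <- simulate_common_drive_emg(cfg)
  r2 <- simulate_common_drive_emg(cfg)
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_common_drive_emg(drive_sim_config(duration_s = 5, seed = 42))
  expect_false(identical(r1$samples, r3$samples))
})

test_that("simulator configs validate their parameter ranges", {
  expect_error(drive_sim_config(kappa = 1.2), "kappa")
  expect_error(drive_sim_config(crosstalk_coeff = 1), "crosstalk")
  expect_error(hreflex_sim_config(m_sd_pct = -1), "nonnegative")
  expect_error(hreflex_sim_config(suppression_fraction = 1.5), "exceed")
})

test_that("uncoupled pools give null-level coherence, coupled pools do not", {
  # kappa = 0, no cross-talk: ~5% of 1-60 Hz bins above the limit
  fr <- vapply(1:8, function(s) {
    est <- analyse_record(simulate_common_drive_emg(drive_sim_config(
      kappa = 0, duration_s = 60, seed = 500 + s)))
    sel <- est$freqs >= 1 & est$freqs <= 60
    mean(est$coherence[sel] > est$coh_cl)
  }, numeric(1))
  expect_lt(mean(fr), 0.12)

  # kappa = 0.8 with dominant beta drive: driven band exceeds the limit,
  # 45-60 Hz mostly does not
  est <- analyse_record(simulate_common_drive_emg(drive_sim_config(
    kappa = 0.8, duration_s = 120, seed = 51)))
  beta <- est$freqs >= 15 & est$freqs <= 35
  high <- est$freqs >= 45 & est$freqs <= 60
  expect_gt(mean(est$coherence[beta] > est$coh_cl), 0.6)
  expect_lt(mean(est$coherence[high] > est$coh_cl), 0.3)
})

test_that("expected beta-band coherence area is nondecreasing in kappa", {
  kappas <- c(0, 0.2, 0.5, 0.8)
  areas <- vapply(kappas, function(k) {
    mean(vapply(1:30, function(s) {
      est <- analyse_record(simulate_common_drive_emg(drive_sim_config(
        kappa = k, duration_s = 60, seed = 600 + 40 * round(10 * k) + s)))
      band_area(est, c(15, 35))$area
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(areas) > -0.02))  # nondecreasing up to MC noise
  expect_gt(areas[4], areas[1])
})

test_that("H-reflex sweeps embed the configured amplitudes exactly at zero noise", {
  cfg <- hreflex_sim_config(n_subjects_per_group = 3, m_sd_pct = 0,
                            h_rest_sd_pct = 0, trial_noise_sd_pct = 0,
                            waveform_noise_sd_mv = 0, seed = 61)
  sets <- simulate_hreflex_dataset(cfg)
  amps <- lapply(sets, extract_reflex_amplitudes)
  for (a in amps) expect_equal(a$m_pct, rep(10, cfg$n_trials_per_state),
                               tolerance = 1e-9)
  rest <- amps[vapply(amps, function(a) a$state == "rest", logical(1))]
  onset <- amps[vapply(amps, function(a) a$state == "onset", logical(1))]
  for (i in seq_along(rest)) {
    expect_equal(mean(onset[[i]]$h_pct) / mean(rest[[i]]$h_pct),
                 1 - cfg$suppression_fraction, tolerance = 1e-9)
  }

  # suppression_fraction = 0: rest and onset H amplitudes coincide
  cfg0 <- hreflex_sim_config(n_subjects_per_group = 2, m_sd_pct = 0,
                             h_rest_sd_pct = 0, trial_noise_sd_pct = 0,
                             waveform_noise_sd_mv = 0,
                             suppression_fraction = 0, seed = 62)
  a0 <- lapply(simulate_hreflex_dataset(cfg0), extract_reflex_amplitudes)
  expect_equal(mean(a0[[1]]$h_pct), mean(a0[[2]]$h_pct), tolerance = 1e-9)
})

test_that("large-trial suppression recovery matches the configured fraction", {
  cfg <- hreflex_sim_config(n_subjects_per_group = 4, n_trials_per_state = 1e4,
                            suppression_fraction = 0.37, seed = 63)
  sets <- simulate_hreflex_dataset(cfg)
  supp <- vapply(seq(1, length(sets), by = 2), function(i) {
    suppression_result(extract_reflex_amplitudes(sets[[i]]),
                       extract_reflex_amplitudes(sets[[i + 1]]))$percent_suppression
  }, numeric(1))
  expect_equal(mean(supp), 37, tolerance = 0.02)
})

test_that("torque trials rise at the configured rate and flag dips", {
  tr <- simulate_torque_trial(rise_rate = 120, peak = 60)
  expect_true(all(diff(tr$torque) >= 0))
  slope <- max(diff(tr$torque)) * tr$fs
  expect_equal(slope, 120, tolerance = 0.01)
  expect_false(detect_countermovement(tr))

  dip <- simulate_torque_trial(rise_rate = 120, peak = 60,
                               countermovement_depth = 2)
  expect_true(detect_countermovement(dip, drop_threshold = 1))
})
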