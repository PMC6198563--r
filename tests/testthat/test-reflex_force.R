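# Windowed sweep with a square biphasic deflection of known peak-to-peak size.
make_sweep <- function(n = 160, fs = 2000, at_s = 0.015, amp = 1) {
  sw <- numeric(n)
  i <- round(at_s * fs) + 1L
  sw[i] <- amp / 2
  sw[i + 2L] <- -amp / 2
  sw
}

test_that("peak-to-peak amplitude follows its definition and scales linearly", {
  fs <- 2000
  t <- seq(0, 0.02 - 1 / fs, by = 1 / fs)
  sine <- sin(2 * pi * 50 * t)  # one full cycle; peaks fall on the grid
  expect_equal(peak_to_peak(sine, c(0, 0.02), fs), 2, tolerance = 1e-9)
  expect_equal(peak_to_peak(rep(3, 100), c(0, 0.02), fs), 0)
  a <- c(0.5, 1, 2, 4)
  p2p <- vapply(a, function(s) peak_to_peak(make_sweep(amp = s),
                                            c(0.005, 0.025), fs), numeric(1))
  expect_equal(p2p, a)
  expect_error(peak_to_peak(sine, c(0.5, 0.6), fs), "window")
})

test_that("M_max is the recruitment plateau with a flag when absent", {
  fs <- 2000
  mk <- function(amp) list(intensity = NA, sweep = make_sweep(amp = amp))
  amps <- c(2, 5, 7.2, 7.96, 8.0, 7.98)
  rec <- lapply(seq_along(amps), function(i) {
    r <- mk(amps[i]); r$intensity <- 5 + i; r
  })
  res <- find_mmax(rec, fs)
  expect_equal(res$m_max, 8.0)
  expect_true(res$plateau)

  rising <- lapply(1:4, function(i) list(intensity = i, sweep = make_sweep(amp = i)))
  expect_warning(res2 <- find_mmax(rising, fs), "plateau")
  expect_equal(res2$m_max, 4)
  expect_false(res2$plateau)

  expect_error(find_mmax(rec[1:2], fs), "at least 3")
})

test_that("percent suppression reproduces printed arithmetic and sign rules", {
  expect_equal(round(percent_suppression(40.7, 25.6)), 37)
  expect_equal(percent_suppression(40.7, 25.6), 37.1, tolerance = 1e-3)
  expect_equal(percent_suppression(10, 10), 0)
  expect_equal(percent_suppression(40, 60), -50)
  expect_error(percent_suppression(0, 5), "positive")
})

test_that("amplitude normalisation is invariant to common rescaling", {
  cfg <- hreflex_sim_config(n_subjects_per_group = 1, seed = 91)
  ss <- simulate_hreflex_dataset(cfg)[[1]]
  a1 <- extract_reflex_amplitudes(ss)
  ss2 <- ss
  ss2$sweeps <- ss$sweeps * 3.7
  ss2$m_max <- ss$m_max * 3.7
  a2 <- extract_reflex_amplitudes(ss2)
  expect_equal(a1$h_pct, a2$h_pct, tolerance = 1e-12)
  expect_equal(a1$m_pct, a2$m_pct, tolerance = 1e-12)
})

test_that("the mixed ANOVA matches a sums-of-squares oracle", {
  # balanced constructed data, 4 subjects per group
  tab <- expand.grid(subject = paste0("S", 1:8), state = c("rest", "onset"))
  tab$group <- ifelse(tab$subject %in% paste0("S", 1:4), "CON", "CP")
  set.seed(92)
  eff <- ifelse(tab$group == "CON" & tab$state == "onset", -12, 0)
  tab$value <- 40 + eff + rep(rnorm(8, sd = 4), 2) + rnorm(16, sd = 2)
  res <- rm_anova_group_state(tab)

  # oracle: for a 2-level within factor, the interaction F equals the
  # between-group one-way F on per-subject state differences
  wide <- reshape(tab, idvar = "subject", timevar = "state",
                  direction = "wide")
  d <- wide$value.rest - wide$value.onset
  g <- wide$group.rest
  gm <- tapply(d, g, mean); n_g <- tapply(d, g, length)
  ssb <- sum(n_g * (gm - mean(d))^2)
  ssw <- sum((d - gm[g])^2)
  F_oracle <- (ssb / 1) / (ssw / (length(d) - 2))
  expect_equal(res$F_interaction, F_oracle, tolerance = 1e-9)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 6)

  # no state effect anywhere: interaction F = 0
  flat <- tab
  flat$value <- 40 + rep(rnorm(8, sd = 4), 2)[as.integer(flat$subject)]
  res0 <- rm_anova_group_state(flat)
  expect_equal(res0$F_interaction, 0)

  # missing cell
  expect_error(rm_anova_group_state(tab[-1, ]), "per state")
})

test_that("simulated group/state datasets yield the expected interaction", {
  hits <- vapply(1:5, function(r) {
    con <- simulate_hreflex_dataset(hreflex_sim_config(
      n_subjects_per_group = 14, suppression_fraction = 0.37, seed = 930 + r))
    cp <- simulate_hreflex_dataset(hreflex_sim_config(
      n_subjects_per_group = 16, suppression_fraction = 0, seed = 960 + r))
    rows <- function(sets, grp, off) do.call(rbind, lapply(sets, function(s) {
      a <- extract_reflex_amplitudes(s)
      data.frame(subject = paste0(grp, a$subject_id), group = grp,
                 state = a$state, value = mean(a$h_pct))
    }))
    tab <- rbind(rows(con, "CON"), rows(cp, "CP"))
    res <- rm_anova_group_state(tab)
    res$F_interaction > qf(0.95, res$df1, res$df2)
  }, logical(1))
  expect_gte(mean(hits), 0.6)
})

test_that("torque metrics recover onset, slope and countermovement rules", {
  tr <- simulate_torque_trial(rise_rate = 150, peak = 60)
  # rfd200 on a linear ramp equals its slope (100 Nm/s)
  ramp <- torque_trial(c(rep(0, 1000), seq(0, 100, length.out = 1001)),
                       fs = 1000, onset_index = 1001)
  expect_equal(rfd200(ramp), 100, tolerance = 1e-9)
  flat <- torque_trial(rep(5, 2000), fs = 1000, onset_index = 500)
  expect_equal(rfd200(flat), 0)

  # smoothstep oracle from the generator's closed form
  rise_s <- 1.5 * 60 / 150
  f <- function(t) {
    u <- pmin(pmax((t - 1) / rise_s, 0), 1)
    60 * (3 * u^2 - 2 * u^3)
  }
  onset_t <- (tr$onset_index - 1) / tr$fs
  expect_equal(rfd200(tr), (f(onset_t + 0.2) - f(onset_t)) / 0.2,
               tolerance = 1e-6)

  # onset detection: step at a known index with zero noise
  step <- torque_trial(c(rep(0, 800), rep(10, 400)), fs = 1000)
  expect_equal(torque_onset(step), 801)
  set.seed(93)
  expect_error(torque_onset(torque_trial(rnorm(2000), fs = 1000)), "onset")
  noisy <- simulate_torque_trial(rise_rate = 400, peak = 60, noise_sd = 0.05,
                                 seed = 94)
  found <- torque_onset(noisy)
  expect_lt(abs(found - noisy$onset_index) / noisy$fs, 0.010)

  # countermovement tie rule: dip exactly at threshold is not flagged
  dipped <- torque_trial(c(rep(0, 700), rep(-1, 100), rep(0, 200),
                           seq(0, 50, length.out = 1000)),
                         fs = 1000, onset_index = 1001)
  expect_false(detect_countermovement(dipped, drop_threshold = 1))
  expect_true(detect_countermovement(dipped, drop_threshold = 0.99))

  # best-trial selection excludes countermovement trials first
  good <- simulate_torque_trial(rise_rate = 120, peak = 55)
  better <- simulate_torque_trial(rise_rate = 120, peak = 60)
  best_bad <- simulate_torque_trial(rise_rate = 120, peak = 70,
                                    countermovement_depth = 5)
  pick <- mvc_peak_torque(list(good, best_bad, better), drop_threshold = 2)
  expect_equal(pick$best_trial_index, 3)
  expect_equal(pick$peak, max(better$torque))
  expect_error(mvc_peak_torque(list(best_bad), drop_threshold = 2), "rejected")
})

test_that("the cocontraction index is a normalised area ratio", {
  fs <- 2000
  n <- 3 * fs
  onset <- fs + 1L
  sol <- rep(0.05, n); ta <- rep(0.5, n)
  # identical normalised envelopes -> 100%
  expect_equal(cocontraction_index(ta, ta, 8, 8, onset, fs), 100,
               tolerance = 1e-9)
  # sol area 5% of its Mmax, ta 50% of its Mmax -> 10%
  expect_equal(cocontraction_index(sol, ta, 8, 8, onset, fs), 10,
               tolerance = 1e-9)
  expect_equal(cocontraction_index(numeric(n), ta, 8, 8, onset, fs), 0)
  expect_error(cocontraction_index(sol, numeric(n), 8, 8, onset, fs), "zero")
})
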