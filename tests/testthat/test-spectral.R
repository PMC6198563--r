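test_that("self-coherence is one and the L=2 confidence limit is exact", {
  set.seed(21)
  x <- normalize_unit_variance(rnorm(10000), fs = 2000)
  est <- estimate_spectra(x, x, resolution_hz = 1)
  expect_true(all(abs(est$coherence[est$f_xx > 0] - 1) < 1e-9))
  expect_true(all(est$coherence >= 0 & est$coherence <= 1))

  est2 <- estimate_spectra(rnorm(4000), rnorm(4000), fs = 2000)
  expect_equal(est2$L, 2L)
  expect_equal(est2$coh_cl, 0.95)

  expect_error(estimate_spectra(rnorm(1000), rnorm(1000), fs = 2000),
               "insufficient")
  a <- normalize_unit_variance(rnorm(4000), fs = 2000)
  b <- normalize_unit_variance(rnorm(4000), fs = 1000)
  expect_error(estimate_spectra(a, b), "mismatched")
})

test_that("independent noise exceeds the 95% limit at about 5% of bins", {
  fr <- vapply(1:20, function(s) {
    set.seed(300 + s)
    est <- estimate_spectra(rnorm(120000), rnorm(120000), fs = 2000)
    sel <- est$freqs >= 1 & est$freqs <= 60
    mean(est$coherence[sel] > est$coh_cl)
  }, numeric(1))
  expect_equal(mean(fr), 0.05, tolerance = 0.3)  # 1200 bin decisions
})

test_that("coherence is invariant to positive rescaling of either signal", {
  set.seed(22)
  x <- rnorm(8000); y <- 0.4 * x + rnorm(8000)
  e1 <- estimate_spectra(x, y, fs = 2000)
  e2 <- estimate_spectra(17 * x, 0.003 * y, fs = 2000)
  expect_equal(e1$coherence, e2$coherence, tolerance = 1e-12)
})

test_that("autospectra satisfy Parseval against segment-mean power", {
  set.seed(23)
  x <- rnorm(14000) * 3 + 1
  est <- estimate_spectra(x, x, fs = 2000)
  xs <- matrix(x[seq_len(est$L * est$T)], nrow = est$T)
  xs <- sweep(xs, 2, colMeans(xs))
  pow <- mean(colMeans(xs^2))
  expect_equal(sum(est$full$f_xx), pow, tolerance = 1e-6)
})

test_that("a pure delay shows up at the right cumulant lag and phase slope", {
  set.seed(24)
  n <- 60000; d <- 14; fs <- 2000
  src <- rnorm(n + d)
  x <- normalize_unit_variance(src[seq_len(n)], fs = fs)
  y <- normalize_unit_variance(c(rep(0, d), src[seq_len(n - d)]), fs = fs)
  est <- estimate_spectra(x, y, resolution_hz = 1)
  cum <- cumulant_density(est)
  pk_lag <- cum$lags[which.max(cum$q)]
  expect_equal(pk_lag * fs, d)

  sel <- est$freqs > 0 & est$freqs < 60  # stay inside one phase wrap
  slope <- stats::coef(stats::lm(est$phase[sel] ~ est$freqs[sel]))[2]
  expect_equal(unname(slope), -2 * pi * d / fs, tolerance = 0.01)
})

test_that("the autocumulant is symmetric about zero lag", {
  set.seed(25)
  x <- normalize_unit_variance(rnorm(20000), fs = 2000)
  est <- estimate_spectra(x, x)
  cum <- cumulant_density(est)
  expect_equal(cum$q, rev(cum$q), tolerance = 1e-9)
  expect_equal(cum$lags, -rev(cum$lags))
})

test_that("cumulant confidence band covers independent signals", {
  cov <- vapply(1:20, function(s) {
    set.seed(400 + s)
    est <- estimate_spectra(rnorm(60000), rnorm(60000), fs = 2000)
    cum <- cumulant_density(est)
    mean(cum$q <= cum$cl_upper & cum$q >= cum$cl_lower)
  }, numeric(1))
  expect_gte(mean(cov), 0.93)
})

test_that("the coherence limit is monotone in L and matches the null quantile", {
  cls <- vapply(c(2, 10, 30, 120), function(L) 1 - 0.05^(1 / (L - 1)),
                numeric(1))
  expect_true(all(diff(cls) < 0))

  # empirical 95th percentile of per-bin null coherence at L = 120
  set.seed(26)
  r2 <- unlist(lapply(1:10, function(s) {
    est <- estimate_spectra(rnorm(240000), rnorm(240000), fs = 2000)
    est$coherence[est$freqs >= 1]
  }))
  emp <- unname(stats::quantile(r2, 0.95))
  expect_equal(emp, 1 - 0.05^(1 / 119), tolerance = 0.1)
})

test_that("cross-talk is flagged by broadband coherence plus a zero-lag peak", {
  mixed <- simulate_common_drive_emg(drive_sim_config(
    kappa = 0.4, crosstalk_coeff = 0.5, duration_s = 60, seed = 31))
  est <- analyse_record(mixed)
  qc <- crosstalk_qc(est, cumulant_density(est))
  expect_true(qc$flagged)
  expect_true(qc$zero_lag_peak)

  indep <- simulate_common_drive_emg(drive_sim_config(
    kappa = 0, crosstalk_coeff = 0, duration_s = 60, seed = 32))
  est0 <- analyse_record(indep)
  qc0 <- crosstalk_qc(est0, cumulant_density(est0))
  expect_false(qc0$flagged)
})

test_that("distinct conduction delays give a clearly nonzero cumulant lag", {
  rec <- simulate_common_drive_emg(drive_sim_config(
    kappa = 0.8, drive_delay_ms = c(5, 12), duration_s = 60, seed = 33))
  est <- analyse_record(rec)
  cum <- cumulant_density(est)
  qc <- crosstalk_qc(est, cum)
  expect_false(qc$zero_lag_peak)
  expect_equal(qc$peak_lag_ms, 7, tolerance = 0.45)  # +/- ~3 ms
})
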