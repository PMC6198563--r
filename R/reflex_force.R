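# H-reflex / M-wave amplitude analysis (functional reciprocal inhibition) and
# torque-based strength metrics (MVC, RFD over the first 200 ms,
# cocontraction index).
#
# All reflex amplitudes are peak-to-peak values normalised to the maximal
# M-response (M_max) of the same muscle, the standard control for electrode
# placement and stimulation efficacy.

#' Maximal M-response from a recruitment series
#'
#' Scans peak-to-peak M-wave amplitudes over monotonically increasing
#' stimulation intensities and declares a plateau when the relative increase
#' between successive intensities stays below `plateau_tol` over the final
#' two steps. Returns the maximum observed amplitude either way; when no
#' plateau is reached the result carries a warning flag.
#'
#' @param recruitment List of `list(intensity = mA, sweep = numeric)` entries
#'   (at least 3), intensities strictly increasing.
#' @param fs Sampling rate in Hz.
#' @param m_window M-wave window `(t_start, t_end)` in seconds post-stimulus.
#' @param plateau_tol Relative-increase tolerance declaring a plateau
#'   (default 0.01).
#' @return List with `m_max` (mV), `plateau` (logical) and the per-intensity
#'   `amplitudes`.
#' @export
find_mmax <- function(recruitment, fs, m_window = c(0.005, 0.025),
                      plateau_tol = 0.01) {
  if (length(recruitment) < 3L) {
    stop("need at least 3 stimulation intensities", call. = FALSE)
  }
  intensities <- vapply(recruitment, function(r) r$intensity, numeric(1))
  if (any(diff(intensities) <= 0)) {
    stop("intensities must be strictly increasing", call. = FALSE)
  }
  amps <- vapply(recruitment,
                 function(r) peak_to_peak(r$sweep, m_window, fs), numeric(1))
  n <- length(amps)
  rel <- abs(diff(amps)) / pmax(amps[-n], .Machine$double.eps)
  plateau <- all(rel[(n - 2):(n - 1)] < plateau_tol)
  if (!plateau) warning("no M-response plateau reached; returning maximum observed")
  list(m_max = max(amps), plateau = plateau, amplitudes = amps)
}

#' Peak-to-peak amplitude within a time window
#'
#' @param sweep Numeric sweep, stimulus at t = 0.
#' @param window `(t_start, t_end)` in seconds post-stimulus; samples in
#'   `[t_start, t_end)` are used.
#' @param fs Sampling rate in Hz.
#' @return `max - min` over the window, in the sweep's units.
#' @export
peak_to_peak <- function(sweep, window, fs) {
  stopifnot_scalar(fs, "fs", positive = TRUE)
  i0 <- floor(window[1] * fs) + 1L
  i1 <- ceiling(window[2] * fs)
  i1 <- min(i1, length(sweep))
  if (i0 > i1 || i0 < 1L) stop("empty analysis window", call. = FALSE)
  seg <- sweep[i0:i1]
  max(seg) - min(seg)
}

#' Per-trial M and H amplitudes from a sweep set
#'
#' Extracts peak-to-peak amplitudes in the M and H windows of every sweep and
#' normalises them to the sweep set's `m_max`.
#'
#' @param ss A [sweep_set()].
#' @return A `reflex_amplitudes` object with `m_pct`, `h_pct` (% of M_max),
#'   `state`, `subject_id`, `n_trials`.
#' @export
extract_reflex_amplitudes <- function(ss) {
  stopifnot(inherits(ss, "sweep_set"))
  m <- apply(ss$sweeps, 1, peak_to_peak, window = ss$m_window, fs = ss$fs)
  h <- apply(ss$sweeps, 1, peak_to_peak, window = ss$h_window, fs = ss$fs)
  structure(
    list(m_pct = 100 * m / ss$m_max, h_pct = 100 * h / ss$m_max,
         state = ss$state, subject_id = ss$subject_id,
         n_trials = nrow(ss$sweeps)),
    class = "reflex_amplitudes")
}

#' @export
print.reflex_amplitudes <- function(x, ...) {
  cat(sprintf(
    "<reflex_amplitudes> %s [%s], %d trials: M %.1f +/- %.1f %%M_max, H %.1f +/- %.1f %%M_max\n",
    x$subject_id, x$state, x$n_trials,
    mean(x$m_pct), stats::sd(x$m_pct) / sqrt(x$n_trials),
    mean(x$h_pct), stats::sd(x$h_pct) / sqrt(x$n_trials)))
  invisible(x)
}

#' Percent H-reflex suppression between rest and movement onset
#'
#' `100 * (rest - onset) / rest`; a negative value signals facilitation
#' rather than suppression.
#'
#' @param rest_mean,onset_mean Mean H-reflex amplitudes in % of M_max;
#'   `rest_mean` must be positive.
#' @return Percent suppression.
#' @export
percent_suppression <- function(rest_mean, onset_mean) {
  stopifnot_scalar(rest_mean, "rest_mean")
  stopifnot_scalar(onset_mean, "onset_mean")
  if (rest_mean <= 0) stop("`rest_mean` must be positive", call. = FALSE)
  100 * (rest_mean - onset_mean) / rest_mean
}

#' Mixed two-way ANOVA: group (between) x state (within)
#'
#' Repeated-measures ANOVA on per-subject mean H-reflex (or M-wave)
#' amplitudes, with group as the between-subject factor and state
#' (rest / onset) as the within-subject factor. The group-by-state
#' interaction F has `(1, N - 2)` degrees of freedom for two groups.
#' Post-hoc within-group paired t-tests on the state contrast are reported
#' without multiplicity correction.
#'
#' @param table Data frame with columns `subject`, `group`, `state`, `value`,
#'   one row per subject-state cell; every subject must have both states.
#' @return An `anova_result` with `F_interaction`, `df1`, `df2`,
#'   `p_interaction`, and per-group post-hoc `p` values.
#' @export
rm_anova_group_state <- function(table) {
  req <- c("subject", "group", "state", "value")
  if (!all(req %in% names(table))) {
    stop("`table` needs columns subject, group, state, value", call. = FALSE)
  }
  table$subject <- factor(table$subject)
  table$group <- factor(table$group)
  table$state <- factor(table$state)
  if (nlevels(table$group) != 2L || nlevels(table$state) != 2L) {
    stop("exactly two groups and two states are required", call. = FALSE)
  }
  counts <- table(table$subject, table$state)
  if (any(counts != 1L)) {
    stop("every subject must contribute exactly one value per state",
         call. = FALSE)
  }
  per_group <- table(unique(table[c("subject", "group")])$group)
  if (any(per_group < 2L)) {
    stop("each group needs at least 2 subjects", call. = FALSE)
  }
  fit <- stats::aov(value ~ group * state + Error(subject), data = table)
  within <- summary(fit)[["Error: Within"]][[1]]
  row <- grep("group:state", rownames(within))
  F_int <- within[row, "F value"]
  df1 <- within[row, "Df"]
  df2 <- within["Residuals", "Df"]
  p_int <- within[row, "Pr(>F)"]
  # degenerate within-subject strata (no state effect anywhere) leave only
  # floating-point residue in the SS; report an exact zero interaction
  tol <- 1e-12 * max(1, sum((table$value - mean(table$value))^2))
  ss_int <- within[row, "Sum Sq"]
  ss_res <- within["Residuals", "Sum Sq"]
  if (ss_int < tol) {
    F_int <- 0; p_int <- 1
  } else if (ss_res < tol || is.na(F_int)) {
    F_int <- Inf; p_int <- 0
  }
  posthoc <- lapply(split(table, table$group), function(g) {
    wide <- stats::reshape(g[c("subject", "state", "value")],
                           idvar = "subject", timevar = "state",
                           direction = "wide")
    v <- wide[, -1, drop = FALSE]
    d <- v[[1]] - v[[2]]
    if (stats::sd(d) == 0) {
      list(p = if (all(d == 0)) 1 else 0, mean_diff = mean(d))
    } else {
      tt <- stats::t.test(v[[1]], v[[2]], paired = TRUE)
      list(p = tt$p.value, mean_diff = mean(d))
    }
  })
  structure(
    list(F_interaction = unname(F_int), df1 = df1, df2 = df2,
         p_interaction = unname(p_int), posthoc = posthoc),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> group x state interaction F(%d,%d) = %.2f, p = %.4g\n",
              x$df1, x$df2, x$F_interaction, x$p_interaction))
  for (g in names(x$posthoc)) {
    cat(sprintf("  post-hoc %s: paired p = %.4g (mean state difference %.2f)\n",
                g, x$posthoc[[g]]$p, x$posthoc[[g]]$mean_diff))
  }
  invisible(x)
}

#' Detect an initial countermovement in a torque trace
#'
#' A countermovement is a visible pre-onset drop of the torque below its
#' baseline; here it is flagged when the torque falls more than
#' `drop_threshold` below the baseline mean anywhere up to the contraction
#' onset (strict inequality).
#'
#' @param trial A [torque_trial()] with `onset_index` set (or detectable via
#'   [torque_onset()]).
#' @param drop_threshold Drop in Nm counting as a countermovement; default
#'   2% of the trial's peak torque.
#' @return Logical.
#' @export
detect_countermovement <- function(trial, drop_threshold = NULL) {
  stopifnot(inherits(trial, "torque_trial"))
  onset <- trial$onset_index
  if (is.null(onset)) onset <- torque_onset(trial)
  if (is.null(drop_threshold)) drop_threshold <- 0.02 * max(trial$torque)
  pre <- trial$torque[seq_len(onset)]
  baseline <- mean(trial$torque[seq_len(max(1L, floor(0.5 * trial$fs)))])
  (baseline - min(pre)) > drop_threshold
}

#' Best maximal-voluntary-contraction trial
#'
#' Excludes trials failing the countermovement check, then returns the trial
#' with the highest peak torque.
#'
#' @param trials List of [torque_trial()] objects.
#' @param drop_threshold Passed to [detect_countermovement()].
#' @return List with `best_trial_index` (into the input list) and `peak` (Nm).
#' @export
mvc_peak_torque <- function(trials, drop_threshold = NULL) {
  if (length(trials) < 1L) stop("need at least one trial", call. = FALSE)
  ok <- !vapply(trials, detect_countermovement, logical(1),
                drop_threshold = drop_threshold)
  if (!any(ok)) stop("all trials rejected for countermovement", call. = FALSE)
  peaks <- vapply(trials, function(t) max(t$torque), numeric(1))
  peaks[!ok] <- -Inf
  i <- which.max(peaks)
  list(best_trial_index = i, peak = peaks[i])
}

#' Contraction onset in a torque (or EMG envelope) trace
#'
#' First sample where the signal exceeds baseline mean +
#' `baseline_sd_mult` standard deviations continuously for at least
#' `min_duration_ms`. The baseline is the first 500 ms of the trace.
#'
#' @param trial A [torque_trial()] or numeric vector.
#' @param fs Sampling rate (taken from the trial when omitted).
#' @param baseline_sd_mult Threshold multiplier (default 2).
#' @param min_duration_ms Required supra-threshold duration (default 10 ms).
#' @return Onset sample index.
#' @export
torque_onset <- function(trial, fs = NULL, baseline_sd_mult = 2,
                         min_duration_ms = 10) {
  if (inherits(trial, "torque_trial")) {
    x <- trial$torque; fs <- trial$fs
  } else {
    x <- as.numeric(trial)
    if (is.null(fs)) stop("`fs` required for a bare vector", call. = FALSE)
  }
  nb <- floor(0.5 * fs)
  if (length(x) <= nb) stop("need at least 500 ms of baseline", call. = FALSE)
  base <- x[seq_len(nb)]
  thr <- mean(base) + baseline_sd_mult * stats::sd(base)
  need <- max(1L, round(min_duration_ms / 1000 * fs))
  above <- x > thr
  run <- 0L
  for (i in (nb + 1L):length(x)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= need) return(i - need + 1L)
  }
  stop("no contraction onset found", call. = FALSE)
}

#' Rate of force development over the first 200 ms
#'
#' `(torque(onset + 0.2 s) - torque(onset)) / 0.2` in Nm/s, a measure of
#' explosive muscle force.
#'
#' @param trial A [torque_trial()] with `onset_index` set.
#' @return RFD in Nm/s.
#' @export
rfd200 <- function(trial) {
  stopifnot(inherits(trial, "torque_trial"))
  onset <- trial$onset_index
  if (is.null(onset)) stop("`onset_index` must be set (see torque_onset)",
                           call. = FALSE)
  i200 <- onset + round(0.2 * trial$fs)
  if (i200 > length(trial$torque)) {
    stop("trace too short: need 200 ms after onset", call. = FALSE)
  }
  (trial$torque[i200] - trial$torque[onset]) / 0.2
}

#' Cocontraction index over the first second of contraction
#'
#' Area of the rectified, smoothed antagonist (soleus) EMG in % of its M_max
#' divided by the corresponding normalised agonist (TA) EMG area, over
#' onset .. onset + 1 s, expressed in percent.
#'
#' @param sol,ta Raw EMG signals in millivolts.
#' @param sol_mmax,ta_mmax Maximal M-responses in millivolts.
#' @param onset Contraction onset sample index.
#' @param fs Sampling rate in Hz.
#' @param window_ms Envelope smoothing window (default 50 ms).
#' @return Cocontraction index in percent.
#' @export
cocontraction_index <- function(sol, ta, sol_mmax, ta_mmax, onset, fs,
                                window_ms = 50) {
  stopifnot_scalar(sol_mmax, "sol_mmax", positive = TRUE)
  stopifnot_scalar(ta_mmax, "ta_mmax", positive = TRUE)
  i1 <- onset + round(fs) - 1L
  if (i1 > length(sol) || i1 > length(ta)) {
    stop("need 1000 ms of signal after onset", call. = FALSE)
  }
  idx <- onset:i1
  env_sol <- smooth_envelope(rectify(sol), window_ms, fs)[idx]
  env_ta <- smooth_envelope(rectify(ta), window_ms, fs)[idx]
  area_sol <- sum(env_sol) / fs / sol_mmax * 100
  area_ta <- sum(env_ta) / fs / ta_mmax * 100
  if (area_ta <= 0) stop("zero agonist EMG area", call. = FALSE)
  100 * area_sol / area_ta
}

#' Summarise H-reflex suppression for one subject
#'
#' @param rest,onset `reflex_amplitudes` for the two states of one subject.
#' @return A `suppression_result` with `rest_mean_pct`, `onset_mean_pct` and
#'   `percent_suppression`.
#' @export
suppression_result <- function(rest, onset) {
  stopifnot(inherits(rest, "reflex_amplitudes"),
            inherits(onset, "reflex_amplitudes"))
  rm <- mean(rest$h_pct); om <- mean(onset$h_pct)
  structure(
    list(subject_id = rest$subject_id,
         rest_mean_pct = rm, onset_mean_pct = om,
         percent_suppression = percent_suppression(rm, om)),
    class = "suppression_result")
}

#' @export
print.suppression_result <- function(x, ...) {
  cat(sprintf(
    "<suppression_result> %s: H %.1f%% M_max at rest -> %.1f%% at onset (%.1f%% suppression)\n",
    x$subject_id, x$rest_mean_pct, x$onset_mean_pct, x$percent_suppression))
  invisible(x)
}
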