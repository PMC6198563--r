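# Data model and text-format I/O for all pipeline stages.
#
# Native interchange format: delimited text (CSV, header row = channel labels)
# for sampled signals, with a JSON sidecar carrying the sampling rate, channel
# roles and trial metadata.  Units are fixed throughout: millivolts for EMG,
# newton-metres for torque, hertz, seconds; sweep time is measured from the
# stimulus artifact (t = 0).

#' Multichannel EMG record
#'
#' Container for a sampled multichannel surface-EMG recording together with
#' the metadata the downstream analyses need (sampling rate, channel labels,
#' subject, group and contraction state).
#'
#' @param samples Numeric matrix, `n_samples x n_channels`, in millivolts.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel labels, e.g.
#'   `c("TA_prox", "TA_dist")`.
#' @param subject_id Subject identifier.
#' @param group Group label, one of `"CP"` or `"CON"`.
#' @param state Contraction state, one of `"rest"`, `"onset"`, `"static"`.
#' @return An object of class `emg_record` with fields `samples`, `fs`,
#'   `channel_labels`, `subject_id`, `group`, `state` and `duration_s`.
#' @examples
#' rec <- emg_record(matrix(rnorm(4000), ncol = 2), fs = 2000,
#'                   channel_labels = c("TA_prox", "TA_dist"))
#' rec$duration_s
#' @export
emg_record <- function(samples, fs, channel_labels,
                       subject_id = "S1", group = c("CON", "CP"),
                       state = c("static", "rest", "onset")) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  stopifnot_scalar(fs, "fs", positive = TRUE)
  group <- match.arg(group)
  state <- match.arg(state)
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != ncol(samples)) {
    stop("`channel_labels` must have one entry per column of `samples`",
         call. = FALSE)
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel labels must be unique", call. = FALSE)
  }
  colnames(samples) <- channel_labels
  obj <- structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         subject_id = as.character(subject_id), group = group, state = state,
         duration_s = nrow(samples) / fs),
    class = "emg_record")
  obj
}

#' @export
print.emg_record <- function(x, ...) {
  cat(sprintf("<emg_record> %s [%s/%s]: %d channel(s) (%s), %.3f s at %g Hz\n",
              x$subject_id, x$group, x$state, ncol(x$samples),
              paste(x$channel_labels, collapse = ", "),
              x$duration_s, x$fs))
  invisible(x)
}

#' Stimulus-locked sweep set
#'
#' A set of stimulus-locked sweeps from one subject and state, with the
#' analysis windows for the M-wave and the H-reflex and the subject's maximal
#' M-response used as the normalisation denominator.  The default windows
#' (M: 5--25 ms, H: 25--55 ms post-stimulus) follow standard soleus latencies
#' and are configurable.
#'
#' @param sweeps Numeric matrix, `n_sweeps x n_samples`, millivolts; the
#'   stimulus artifact is at t = 0 (first column).
#' @param fs Sampling rate in Hz.
#' @param state `"rest"` or `"onset"`.
#' @param m_window,h_window Two-element numeric vectors `(t_start, t_end)` in
#'   seconds post-stimulus; `m_window` must precede `h_window` and both must
#'   lie within the sweep extent.
#' @param m_max Maximal M-response in millivolts (normalisation denominator).
#' @param subject_id Subject identifier.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, fs, state = c("rest", "onset"),
                      m_window = c(0.005, 0.025), h_window = c(0.025, 0.055),
                      m_max, subject_id = "S1") {
  sweeps <- as.matrix(sweeps)
  storage.mode(sweeps) <- "double"
  stopifnot_scalar(fs, "fs", positive = TRUE)
  stopifnot_scalar(m_max, "m_max", positive = TRUE)
  state <- match.arg(state)
  if (length(m_window) != 2L || length(h_window) != 2L ||
      m_window[1] >= m_window[2] || h_window[1] >= h_window[2]) {
    stop("M and H windows must be increasing (t_start, t_end) pairs",
         call. = FALSE)
  }
  if (m_window[2] > h_window[1] + 1e-12) {
    stop("the M window must precede the H window", call. = FALSE)
  }
  extent <- ncol(sweeps) / fs
  if (h_window[2] > extent + 1e-12 || m_window[1] < 0) {
    stop("analysis windows must lie within the sweep extent", call. = FALSE)
  }
  structure(
    list(sweeps = sweeps, fs = fs, state = state,
         m_window = as.numeric(m_window), h_window = as.numeric(h_window),
         m_max = m_max, subject_id = as.character(subject_id)),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set> %s [%s]: %d sweeps of %.0f ms at %g Hz, M %g-%g ms, H %g-%g ms, M_max %.2f mV\n",
    x$subject_id, x$state, nrow(x$sweeps), 1000 * ncol(x$sweeps) / x$fs, x$fs,
    1000 * x$m_window[1], 1000 * x$m_window[2],
    1000 * x$h_window[1], 1000 * x$h_window[2], x$m_max))
  invisible(x)
}

#' Torque trial
#'
#' A single dorsiflexion torque trace in newton-metres, optionally with a
#' known contraction-onset sample index.
#'
#' @param torque Numeric vector, Nm.
#' @param fs Sampling rate in Hz.
#' @param onset_index Optional sample index of contraction onset.
#' @return An object of class `torque_trial`.
#' @export
torque_trial <- function(torque, fs, onset_index = NULL) {
  torque <- as.numeric(torque)
  stopifnot_scalar(fs, "fs", positive = TRUE)
  if (!is.null(onset_index)) {
    stopifnot_scalar(onset_index, "onset_index")
    if (onset_index < 1 || onset_index > length(torque)) {
      stop("`onset_index` must lie within the trace", call. = FALSE)
    }
    onset_index <- as.integer(onset_index)
  }
  structure(list(torque = torque, fs = fs, onset_index = onset_index),
            class = "torque_trial")
}

#' Analysis configuration
#'
#' Bundles the tunable analysis parameters: spectral resolution, the alpha and
#' beta coherence bands, cumulant lag range, confidence level, reflex windows
#' and the master seed.
#'
#' @param freq_resolution_hz Spectral resolution in Hz (segment length is
#'   `fs / freq_resolution_hz` samples). Default 1 Hz.
#' @param alpha_band,beta_band Two-element vectors in Hz. Defaults 5--15 and
#'   15--35 Hz; the shared 15 Hz bin is assigned to the beta band only (see
#'   [band_area()]).
#' @param cumulant_lag_s Half-width of the cumulant lag range in seconds
#'   (default 0.25, i.e. +/-250 ms).
#' @param confidence_alpha Significance level for all confidence limits.
#' @param m_window,h_window Default reflex analysis windows, seconds
#'   post-stimulus.
#' @param seed Master seed for simulation work.
#' @return An object of class `analysis_config` (a named list).
#' @export
analysis_config <- function(freq_resolution_hz = 1,
                            alpha_band = c(5, 15), beta_band = c(15, 35),
                            cumulant_lag_s = 0.25, confidence_alpha = 0.05,
                            m_window = c(0.005, 0.025),
                            h_window = c(0.025, 0.055),
                            seed = 1L) {
  stopifnot_scalar(freq_resolution_hz, "freq_resolution_hz", positive = TRUE)
  stopifnot_scalar(cumulant_lag_s, "cumulant_lag_s", positive = TRUE)
  stopifnot_scalar(confidence_alpha, "confidence_alpha")
  if (confidence_alpha <= 0 || confidence_alpha >= 1) {
    stop("`confidence_alpha` must lie strictly between 0 and 1", call. = FALSE)
  }
  for (b in list(alpha_band, beta_band)) {
    if (length(b) != 2L || b[1] >= b[2]) {
      stop("bands must be increasing (lo, hi) pairs in Hz", call. = FALSE)
    }
  }
  structure(
    list(freq_resolution_hz = freq_resolution_hz,
         alpha_band = as.numeric(alpha_band), beta_band = as.numeric(beta_band),
         cumulant_lag_s = cumulant_lag_s, confidence_alpha = confidence_alpha,
         m_window = as.numeric(m_window), h_window = as.numeric(h_window),
         seed = as.integer(seed)),
    class = "analysis_config")
}

#' Read a multichannel EMG record from CSV + JSON sidecar
#'
#' The CSV holds one column per channel (header row = channel labels); the
#' JSON sidecar supplies `fs` (required) and optionally `subject_id`, `group`
#' and `state`.
#'
#' @param path Path to the CSV signal file.
#' @param meta_path Path to the JSON metadata file; defaults to `path` with
#'   the extension replaced by `.json`.
#' @return An [emg_record()].
#' @seealso [write_emg()]
#' @export
read_emg <- function(path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.[^.]+$", ".json", path)
  if (!file.exists(meta_path)) {
    stop(sprintf("metadata file not found: %s", meta_path), call. = FALSE)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) {
    stop("metadata must supply the sampling rate `fs`", call. = FALSE)
  }
  dat <- utils::read.csv(path, check.names = FALSE)
  labels <- if (!is.null(meta$channel_labels)) meta$channel_labels else names(dat)
  emg_record(as.matrix(dat), fs = meta$fs, channel_labels = labels,
             subject_id = if (is.null(meta$subject_id)) "S1" else meta$subject_id,
             group = if (is.null(meta$group)) "CON" else meta$group,
             state = if (is.null(meta$state)) "static" else meta$state)
}

#' Write a multichannel EMG record to CSV + JSON sidecar
#'
#' @param rec An [emg_record()].
#' @param path Output CSV path; the JSON sidecar is written next to it.
#' @return Invisibly, the two file paths.
#' @export
write_emg <- function(rec, path) {
  stopifnot(inherits(rec, "emg_record"))
  df <- as.data.frame(rec$samples)
  names(df) <- rec$channel_labels
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta_path <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(fs = rec$fs, channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, group = rec$group, state = rec$state,
         duration_s = rec$duration_s),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, meta_path))
}

#' Serialise a pipeline result to JSON
#'
#' Writes any finished result object of the pipeline (spectral estimates,
#' pooled comparisons, reflex summaries, ...) as structured JSON, embedding
#' the analysis configuration and seed when supplied so a run can be
#' reproduced from its output.
#'
#' @param obj A result object (any S3 object built from lists/vectors).
#' @param path Output path.
#' @param config Optional [analysis_config()] snapshot to embed.
#' @return Invisibly, `path`.
#' @seealso [read_results()]
#' @export
write_results <- function(obj, path, config = NULL) {
  payload <- list(class = class(obj)[1], result = strip_class(obj))
  if (!is.null(config)) payload$config <- strip_class(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", complex = "list")
  invisible(path)
}

#' Read back a serialised pipeline result
#'
#' @param path Path written by [write_results()].
#' @return A list with elements `class`, `result` and (if embedded) `config`.
#' @export
read_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# Recursively drop S3 classes so jsonlite serialises plain structures; complex
# vectors are split into re/im parts.
strip_class <- function(x) {
  if (is.complex(x)) return(list(re = Re(x), im = Im(x)))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, strip_class))
  }
  x
}
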