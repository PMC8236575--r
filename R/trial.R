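#' Default electrode channel names
#'
#' Seven surface electrodes over the shoulder and forearm muscles used for
#' upper-limb motion recognition.
#'
#' @return Character vector of length 7.
#' @export
emg_channel_names <- function() {
  c(
    "anterior_deltoid", "middle_deltoid", "posterior_deltoid",
    "biceps", "triceps", "brachioradialis", "flexor_carpi_radialis"
  )
}

#' Default motion class labels
#'
#' The eleven shoulder/elbow motion classes: shoulder flexion (SF), shoulder
#' abduction (SA), shoulder posterior flexion (SPF), elbow flexion (EF),
#' elbow extension (EE), and the six pairwise shoulder+elbow combinations.
#'
#' @return Character vector of length 11.
#' @export
emg_motion_labels <- function() {
  c(
    "SF", "SA", "SPF", "EF", "EE",
    "SFEF", "SFEE", "SAEF", "SAEE", "SPFEF", "SPFEE"
  )
}

#' Construct a single-trial EMG recording
#'
#' An `emg_trial` holds one multichannel recording of one repetition of one
#' motion: a channels-by-samples matrix plus acquisition metadata.
#'
#' @param samples Numeric matrix, channels in rows, time samples in columns.
#' @param sampling_rate Sampling rate in Hz.
#' @param motion Motion class label.
#' @param trial_index Repetition index of this motion within the session.
#' @param day Session day (1-based).
#' @param subject Subject identifier.
#' @param channel_names Character vector naming the rows of `samples`.
#'
#' @return An object of class `emg_trial`.
#' @export
emg_trial <- function(samples, sampling_rate, motion,
                      trial_index = 1L, day = 1L, subject = "S1",
                      channel_names = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    abort("`samples` must be a finite numeric matrix (channels x time).")
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(samples) == 7L) emg_channel_names() else
      paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples)) {
    abort("`channel_names` length must equal the number of channel rows.")
  }
  rownames(samples) <- channel_names
  structure(
    list(
      samples = samples,
      sampling_rate = as.numeric(sampling_rate),
      motion = as.character(motion),
      trial_index = as.integer(trial_index),
      day = as.integer(day),
      subject = as.character(subject),
      channel_names = channel_names
    ),
    class = "emg_trial"
  )
}

#' @export
print.emg_trial <- function(x, ...) {
  cat(sprintf(
    "<emg_trial> subject %s, day %d, motion %s, trial %d: %d channels x %d samples @ %g Hz\n",
    x$subject, x$day, x$motion, x$trial_index,
    nrow(x$samples), ncol(x$samples), x$sampling_rate
  ))
  invisible(x)
}

#' Sliding-window specification
#'
#' @param length_ms Window length in milliseconds (default 250 ms, i.e. 375
#'   samples at 1500 Hz).
#' @param step_ms Step between consecutive window starts in milliseconds
#'   (default 50 ms, so consecutive 250-ms windows overlap by 200 ms).
#'
#' @return An object of class `emg_window_spec`.
#' @export
window_spec <- function(length_ms = 250, step_ms = 50) {
  if (!(step_ms > 0 && step_ms <= length_ms)) {
    abort("`step_ms` must satisfy 0 < step_ms <= length_ms.")
  }
  structure(list(length_ms = length_ms, step_ms = step_ms),
            class = "emg_window_spec")
}

window_samples <- function(spec, sampling_rate) {
  n <- spec$length_ms * sampling_rate / 1000
  s <- spec$step_ms * sampling_rate / 1000
  if (abs(n - round(n)) > 1e-9 || abs(s - round(s)) > 1e-9) {
    abort(sprintf(
      "Window of %g/%g ms is not a whole number of samples at %g Hz.",
      spec$length_ms, spec$step_ms, sampling_rate
    ))
  }
  list(n = as.integer(round(n)), step = as.integer(round(s)))
}

#' Expected number of sliding windows
#'
#' Closed-form count `floor((L - N) / step) + 1` for a signal of `L` samples
#' cut into windows of `N` samples advancing by `step`.
#'
#' @param l_samples Signal length in samples.
#' @param n_samples Window length in samples.
#' @param step_samples Step in samples.
#' @return Integer window count.
#' @export
n_windows <- function(l_samples, n_samples, step_samples) {
  if (l_samples < n_samples) return(0L)
  as.integer((l_samples - n_samples) %/% step_samples + 1L)
}

#' Segment a trial into overlapping windows
#'
#' Cuts the central `keep_central_s` seconds of a trial into sliding windows.
#' At the defaults (7-s trial at 1500 Hz, central 5 s, 250-ms windows every
#' 50 ms) each trial yields 96 windows of 375 samples.
#'
#' @param trial An [emg_trial()].
#' @param spec An [window_spec()].
#' @param keep_central_s Length of the central span to keep, in seconds.
#'   `NULL` keeps the whole trial.
#'
#' @return A tibble with one row per window: `subject`, `day`, `motion`,
#'   `trial`, `window`, and a `samples` list-column of channels-by-N matrices.
#' @export
segment_trial <- function(trial, spec = window_spec(), keep_central_s = NULL) {
  stopifnot(inherits(trial, "emg_trial"), inherits(spec, "emg_window_spec"))
  ws <- window_samples(spec, trial$sampling_rate)
  x <- trial$samples
  total <- ncol(x)
  if (!is.null(keep_central_s)) {
    kept <- keep_central_s * trial$sampling_rate
    if (abs(kept - round(kept)) > 1e-9) {
      abort(sprintf(
        "keep_central_s = %g s is not a whole number of samples at %g Hz.",
        keep_central_s, trial$sampling_rate
      ))
    }
    kept <- as.integer(round(kept))
    if (kept > total) {
      abort(sprintf(
        "Trial has %d samples (%.3g s); cannot keep a central span of %g s.",
        total, total / trial$sampling_rate, keep_central_s
      ))
    }
    start <- (total - kept) %/% 2L
    x <- x[, (start + 1L):(start + kept), drop = FALSE]
  }
  l <- ncol(x)
  if (l < ws$n) {
    abort(sprintf("Kept span (%d samples) is shorter than one window (%d).",
                  l, ws$n))
  }
  k <- n_windows(l, ws$n, ws$step)
  starts <- (seq_len(k) - 1L) * ws$step
  wins <- lapply(starts, function(s0) x[, (s0 + 1L):(s0 + ws$n), drop = FALSE])
  tibble::tibble(
    subject = trial$subject,
    day = trial$day,
    motion = trial$motion,
    trial = trial$trial_index,
    window = seq_len(k),
    samples = wins
  )
}

#' Segment every trial of a session table
#'
#' @param sessions A tibble with a `recording` list-column of [emg_trial()]
#'   objects, as returned by [generate_benchmark()] or [read_session_csv()].
#' @inheritParams segment_trial
#' @return Row-bound tibble of [segment_trial()] results.
#' @export
segment_session <- function(sessions, spec = window_spec(),
                            keep_central_s = NULL) {
  stopifnot(is.data.frame(sessions), "recording" %in% names(sessions))
  dplyr::bind_rows(
    lapply(sessions$recording, segment_trial,
           spec = spec, keep_central_s = keep_central_s)
  )
}
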