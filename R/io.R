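#' Write / read raw sessions as per-trial CSV files
#'
#' One CSV per trial (columns = channels, header = muscle names) plus a
#' `manifest.csv` with the trial metadata. Reading validates the channel
#' count and restores the session tibble; the round trip preserves sample
#' values to full printed precision.
#'
#' @param sessions Session tibble with a `recording` list-column.
#' @param dir Directory to write into (created if missing).
#' @return `write_session_csv` returns `dir` invisibly; `read_session_csv`
#'   returns the session tibble.
#' @export
write_session_csv <- function(sessions, dir) {
  stopifnot(is.data.frame(sessions), "recording" %in% names(sessions))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- purrr::map_dfr(sessions$recording, function(tr) {
    fname <- sprintf("%s_D%d_M%s_T%d.csv", tr$subject, tr$day, tr$motion,
                     tr$trial_index)
    df <- tibble::as_tibble(t(tr$samples), .name_repair = "minimal")
    names(df) <- tr$channel_names
    readr::write_csv(df, file.path(dir, fname), progress = FALSE)
    tibble::tibble(
      file = fname, subject = tr$subject, day = tr$day, motion = tr$motion,
      trial = tr$trial_index, sampling_rate = tr$sampling_rate,
      channels = nrow(tr$samples)
    )
  })
  readr::write_csv(manifest, file.path(dir, "manifest.csv"), progress = FALSE)
  invisible(dir)
}

#' @rdname write_session_csv
#' @param channels Required channel count; a trial file with a different
#'   number of columns is a schema error.
#' @export
read_session_csv <- function(dir, channels = 7L) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) abort(sprintf("No manifest.csv found in '%s'.", dir))
  manifest <- readr::read_csv(mf, show_col_types = FALSE, progress = FALSE)
  required <- c("file", "subject", "day", "motion", "trial", "sampling_rate")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0L) {
    abort(sprintf("manifest.csv lacks required fields: %s.",
                  paste(missing, collapse = ", ")))
  }
  rows <- purrr::pmap(manifest, function(file, subject, day, motion, trial,
                                         sampling_rate, ...) {
    df <- readr::read_csv(file.path(dir, file), show_col_types = FALSE,
                          progress = FALSE)
    if (ncol(df) != channels) {
      abort(sprintf("Trial '%s' has %d channels; expected %d.",
                    file, ncol(df), channels))
    }
    tr <- emg_trial(t(as.matrix(df)), sampling_rate, motion,
                    trial_index = trial, day = day, subject = subject,
                    channel_names = names(df))
    tibble::tibble(subject = subject, day = day, motion = motion,
                   trial = trial, recording = list(tr))
  })
  dplyr::bind_rows(rows)
}

#' Write / read feature tables as CSV
#'
#' Column order is `dim_0001..dim_NNNN, label, subject, day, trial, window`.
#'
#' @param features Feature tibble from [extract_features()].
#' @param path CSV file path.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Band-pass and notch filter for external raw recordings
#'
#' Zero-phase Butterworth band-pass (20-450 Hz by default) plus a 50-Hz
#' band-stop, the acquisition-side conditioning assumed by the rest of the
#' pipeline. Synthetic trials are generated band-limited already, so this
#' utility is only needed for recordings arriving unfiltered.
#'
#' @param x An [emg_trial()] or a channels-by-samples matrix.
#' @param sampling_rate Sampling rate in Hz (taken from the trial if given).
#' @param low,high Band edges in Hz.
#' @param notch Mains frequency to suppress (`NULL` to skip), +-2 Hz.
#' @return Filtered object of the same type.
#' @export
emg_bandpass <- function(x, sampling_rate = 1500, low = 20, high = 450,
                         notch = 50) {
  is_trial <- inherits(x, "emg_trial")
  if (is_trial) {
    sampling_rate <- x$sampling_rate
    mat <- x$samples
  } else {
    mat <- as.matrix(x)
  }
  nyq <- sampling_rate / 2
  bp <- signal::butter(2, c(low, high) / nyq, type = "pass")
  bs <- if (!is.null(notch)) {
    signal::butter(2, c(notch - 2, notch + 2) / nyq, type = "stop")
  }
  for (c in seq_len(nrow(mat))) {
    row <- signal::filtfilt(bp, mat[c, ])
    if (!is.null(bs)) row <- signal::filtfilt(bs, row)
    mat[c, ] <- row
  }
  if (is_trial) {
    x$samples <- mat
    rownames(x$samples) <- x$channel_names
    x
  } else {
    mat
  }
}
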