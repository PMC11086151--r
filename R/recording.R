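#' Multichannel EEG recording
#'
#' Container for a referential scalp EEG recording: a channel-by-sample
#' matrix in microvolts with its sampling rate and channel labels.
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row names,
#'   if present, must equal `channels`.
#' @param fs Sampling rate in Hz (clinical acquisition uses 250 or 1000).
#' @param channels Character vector of electrode labels, one per row.
#' @param subject_id,event_id Identifiers carried through manifests.
#' @return An object of class `eeg_recording` with fields `data`, `fs`,
#'   `channels`, `subject_id`, `event_id`.
#' @export
eeg_recording <- function(data, fs, channels = eeg_channels(),
                          subject_id = "S0", event_id = "E0") {
  data <- as.matrix(data)
  if (nrow(data) != length(channels))
    stop("row count (", nrow(data), ") must equal number of channels (",
         length(channels), ")")
  if (anyDuplicated(channels)) stop("channel labels must be unique")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (!all(is.finite(data))) stop("all sample values must be finite")
  rownames(data) <- channels
  structure(
    list(data = data, fs = fs, channels = channels,
         subject_id = subject_id, event_id = event_id),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s/%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$event_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Event annotation
#'
#' Ground-truth annotation for one clinical event: its type (epileptic
#' seizure, ES, or psychogenic non-epileptic seizure, PNES) and the
#' half-open time intervals, in seconds, of electrographic ictal activity
#' and of movement/EMG artifact.
#'
#' ES events must carry at least one ictal interval; PNES events, which by
#' definition lack an electrographic correlate, must carry none.
#'
#' @param event_type `"ES"` or `"PNES"`.
#' @param ictal_intervals List of `(start_s, end_s)` pairs (or n x 2 matrix).
#' @param artifact_intervals List of `(start_s, end_s)` pairs.
#' @param duration_s Recording duration; intervals must lie inside it.
#' @return An object of class `event_annotation`.
#' @export
event_annotation <- function(event_type, ictal_intervals = NULL,
                             artifact_intervals = NULL, duration_s = Inf) {
  event_type <- match.arg(event_type, c("ES", "PNES"))
  ictal <- as_interval_matrix(ictal_intervals)
  artifact <- as_interval_matrix(artifact_intervals)
  for (iv in list(ictal, artifact)) {
    if (nrow(iv) > 0 && (any(iv[, 1] < 0) || any(iv[, 2] > duration_s)))
      stop("intervals must lie within [0, duration_s]")
  }
  if (event_type == "ES" && nrow(ictal) == 0L)
    stop("ES events must have at least one ictal interval")
  if (event_type == "PNES" && nrow(ictal) > 0L)
    stop("PNES events must have no ictal intervals")
  structure(
    list(event_type = event_type, ictal_intervals = ictal,
         artifact_intervals = artifact, duration_s = duration_s),
    class = "event_annotation")
}

#' @export
print.event_annotation <- function(x, ...) {
  cat(sprintf("<event_annotation> %s: %d ictal, %d artifact interval(s)\n",
              x$event_type, nrow(x$ictal_intervals), nrow(x$artifact_intervals)))
  invisible(x)
}
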