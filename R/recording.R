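#' Multichannel EEG recording
#'
#' Container for a channels-by-samples EEG matrix in microvolts with its
#' sampling rate, channel labels, and the name of the reference used.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_names character vector, one label per matrix row.
#' @param reference_name label of the reference, or `"none"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names, reference_name = "none") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  if (nrow(data) != length(channel_names)) {
    stop("data has ", nrow(data), " rows but ", length(channel_names),
         " channel names", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("fs must be a positive scalar", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("data contains NaN/Inf", call. = FALSE)
  }
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs,
         channel_names = as.character(channel_names),
         reference_name = as.character(reference_name)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), ref %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference_name))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  ncol(recording$data) / recording$fs
}

#' Event list
#'
#' Timestamped markers: cues, ground-truth intents, detections, knee events.
#' Stored as a plain data frame with columns `onset` (s), `duration` (s) and
#' `label`, time-ordered.
#'
#' @param onset numeric onsets in seconds (>= 0).
#' @param duration numeric durations in seconds.
#' @param label character labels.
#' @return A data frame of class `event_list`.
#' @export
event_list <- function(onset = numeric(), duration = numeric(),
                       label = character()) {
  if (any(onset < 0)) stop("event onsets must be >= 0", call. = FALSE)
  df <- data.frame(onset = as.numeric(onset),
                   duration = as.numeric(duration),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_list", "data.frame")
  df
}

#' Epoched EEG data
#'
#' Cue-locked trials cut from a continuous recording: a trials x channels x
#' samples array plus the epoch window relative to event onset.
#'
#' @param data numeric array, trials x channels x samples.
#' @param tmin,tmax epoch window in seconds relative to event onset.
#' @param labels per-trial label vector.
#' @param fs sampling rate in Hz.
#' @param channel_names channel labels.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, tmin, tmax, labels, fs, channel_names) {
  if (tmin >= tmax) stop("tmin must be < tmax", call. = FALSE)
  n_expected <- round((tmax - tmin) * fs)
  if (length(dim(data)) != 3L) stop("data must be a 3-d array", call. = FALSE)
  if (dim(data)[3] != n_expected) {
    stop("epoch length ", dim(data)[3], " != round((tmax-tmin)*fs) = ",
         n_expected, call. = FALSE)
  }
  if (dim(data)[1] != length(labels)) {
    stop("trial count ", dim(data)[1], " != label count ", length(labels),
         call. = FALSE)
  }
  structure(
    list(data = data, tmin = tmin, tmax = tmax,
         labels = as.character(labels), fs = fs,
         channel_names = as.character(channel_names)),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples, [%g, %g) s @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$tmin, x$tmax, x$fs))
  if (length(x$labels)) print(table(x$labels))
  invisible(x)
}

#' Epoch time axis
#' @param epochs an [eeg_epochs()] object.
#' @return sample times in seconds relative to event onset (window starts).
#' @export
epoch_times <- function(epochs) {
  epochs$tmin + (seq_len(dim(epochs$data)[3]) - 1L) / epochs$fs
}

#' Read/write an events table
#'
#' Tab-separated file with header `onset  duration  label`, times in seconds
#' with a decimal point, UTF-8.
#'
#' @param events an [event_list()] data frame.
#' @param path file path.
#' @return `read_events` returns an [event_list()]; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)[, c("onset", "duration", "label")]
  # fixed-format numbers so repeated runs are byte-identical
  df$onset <- sprintf("%.6f", df$onset)
  df$duration <- sprintf("%.6f", df$duration)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("onset\tduration\tlabel",
               paste(df$onset, df$duration, df$label, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = c("numeric", "numeric", "character"))
  event_list(df$onset, df$duration, df$label)
}
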