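#' Re-reference a recording
#'
#' Subtracts a reference series from every channel (e.g. a recorded CZA
#' electrode), updating `reference_name`.
#'
#' @param recording an [eeg_recording()].
#' @param reference_channel_data numeric series, same length as the
#'   recording.
#' @param reference_name label stored on the result.
#' @return An [eeg_recording()].
#' @export
rereference <- function(recording, reference_channel_data,
                        reference_name = "custom") {
  n <- ncol(recording$data)
  if (length(reference_channel_data) != n) {
    stop("reference series length (", length(reference_channel_data),
         ") != recording sample count (", n, ")", call. = FALSE)
  }
  eeg_recording(sweep(recording$data, 2L, reference_channel_data),
                recording$fs, recording$channel_names, reference_name)
}

#' Bandpass filter specification
#'
#' Butterworth design. `zero_phase_offline` applies the filter forward and
#' backward (zero group delay, effective order doubled); `causal_online`
#' applies it forward only, using only past samples.
#'
#' @param low_cut,high_cut passband edges, Hz.
#' @param order Butterworth order per edge (even, >= 2; default 4).
#' @param mode `"zero_phase_offline"` or `"causal_online"`.
#' @return list of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 1, high_cut = 100, order = 4,
                        mode = c("zero_phase_offline", "causal_online")) {
  mode <- match.arg(mode)
  if (!(low_cut > 0 && high_cut > low_cut)) {
    stop("require 0 < low_cut < high_cut", call. = FALSE)
  }
  if (order < 2 || order %% 2 != 0) {
    stop("order must be even and >= 2", call. = FALSE)
  }
  structure(list(low_cut = low_cut, high_cut = high_cut, order = order,
                 mode = mode),
            class = "filter_spec")
}

design_butter <- function(spec, fs) {
  signal::butter(spec$order, c(spec$low_cut, spec$high_cut) / (fs / 2),
                 type = "pass")
}

# zero-phase path: demean, odd-reflection pad (suppresses edge transients of
# the slow high-pass pole), filter forward and backward, strip the padding
apply_filter <- function(x, bf, zero_phase, fs, low_cut) {
  if (!zero_phase) {
    return(as.numeric(signal::filter(bf, x)))
  }
  x <- x - mean(x)
  n <- length(x)
  p <- min(n - 1L, ceiling(3 * fs / low_cut))
  xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filter(bf, xp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(p + 1):(p + n)]
}

#' Bandpass-filter a recording
#'
#' @param recording an [eeg_recording()].
#' @param spec a [filter_spec()]; `high_cut` must be below `fs/2`.
#' @return A filtered [eeg_recording()]. The first/last second carry filter
#'   transients; downstream analyses should discard them.
#' @export
bandpass <- function(recording, spec = filter_spec()) {
  fs <- recording$fs
  if (spec$high_cut >= fs / 2) {
    stop("invalid argument: high_cut (", spec$high_cut,
         " Hz) must be below fs/2 (", fs / 2, " Hz)", call. = FALSE)
  }
  bf <- design_butter(spec, fs)
  zero_phase <- spec$mode == "zero_phase_offline"
  out <- t(apply(recording$data, 1L, apply_filter, bf = bf,
                 zero_phase = zero_phase, fs = fs,
                 low_cut = spec$low_cut))
  eeg_recording(out, fs, recording$channel_names, recording$reference_name)
}

#' Small-Laplacian spatial filter
#'
#' Each channel minus the mean of its montage neighbors; sharpens focal
#' activity and improves the signal-to-noise ratio of the sensorimotor
#' rhythm. Channels without neighbors pass through unchanged and are listed
#' in the `"passthrough"` attribute of the result.
#'
#' @param recording an [eeg_recording()].
#' @param montage a [montage_spec()] whose neighbor labels are all recording
#'   channels.
#' @return An [eeg_recording()].
#' @export
laplacian <- function(recording, montage = default_montage()) {
  ch <- recording$channel_names
  nb_all <- unlist(montage$neighbor_map, use.names = FALSE)
  missing <- setdiff(nb_all, ch)
  if (length(missing)) {
    stop("neighbor channel(s) absent from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- recording$data
  passthrough <- character()
  for (i in seq_along(ch)) {
    nb <- montage$neighbor_map[[ch[i]]]
    if (is.null(nb) || !length(nb)) {
      passthrough <- c(passthrough, ch[i])
      next
    }
    nb_mean <- colMeans(recording$data[match(nb, ch), , drop = FALSE])
    out[i, ] <- recording$data[i, ] - nb_mean
  }
  res <- eeg_recording(out, recording$fs, ch, recording$reference_name)
  attr(res, "passthrough") <- passthrough
  res
}

#' Cut cue-locked epochs from a continuous recording
#'
#' Trial k covers `[onset_k + tmin, onset_k + tmax)`, onset mapped to samples
#' via `round(onset * fs)` (0-based, half-open). Events whose window falls
#' outside the recording are dropped with a warning; the drop count is in
#' the `"n_dropped"` attribute.
#'
#' @param recording an [eeg_recording()].
#' @param events an [event_list()].
#' @param tmin,tmax epoch window in seconds relative to onset (`tmin < tmax`).
#' @param labels_filter optional character vector; keep only these labels.
#' @return An [eeg_epochs()] object.
#' @export
epoch <- function(recording, events, tmin, tmax, labels_filter = NULL) {
  if (tmin >= tmax) {
    stop("invalid argument: tmin must be < tmax", call. = FALSE)
  }
  ev <- as.data.frame(events)
  if (!is.null(labels_filter)) {
    ev <- ev[ev$label %in% labels_filter, , drop = FALSE]
  }
  fs <- recording$fs
  n_epoch <- round((tmax - tmin) * fs)
  n_total <- ncol(recording$data)
  starts <- round(ev$onset * fs) + round(tmin * fs)     # 0-based
  ok <- starts >= 0 & (starts + n_epoch) <= n_total
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(n_dropped, " event(s) dropped: epoch window outside recording",
            call. = FALSE)
  }
  ev <- ev[ok, , drop = FALSE]
  starts <- starts[ok]
  n_ch <- nrow(recording$data)
  dat <- array(0, dim = c(nrow(ev), n_ch, n_epoch))
  for (k in seq_len(nrow(ev))) {
    dat[k, , ] <- recording$data[, starts[k] + seq_len(n_epoch),
                                 drop = FALSE]
  }
  res <- eeg_epochs(dat, tmin, tmax, ev$label, fs, recording$channel_names)
  attr(res, "n_dropped") <- n_dropped
  res
}
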