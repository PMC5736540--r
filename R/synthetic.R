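#' Background noise specification
#'
#' Amplitudes of the stochastic background components: 1/f ("pink") noise,
#' broadband white noise (amplifier floor), and an optional mains line
#' component. All amplitudes are RMS microvolts per channel. The defaults are
#' the package's "clinic" signal-to-noise preset; set all amplitudes to zero
#' for the noiseless limit used in oracle tests.
#'
#' @param pink_amplitude RMS amplitude of the 1/f component, uV.
#' @param white_amplitude RMS amplitude of the white component, uV.
#' @param line_freq mains frequency in Hz, or `NULL` for none.
#' @param line_amplitude RMS amplitude of the mains component, uV.
#' @return list of class `noise_spec`.
#' @export
noise_spec <- function(pink_amplitude = 3, white_amplitude = 0.25,
                       line_freq = NULL, line_amplitude = 0) {
  if (pink_amplitude < 0 || white_amplitude < 0 || line_amplitude < 0) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(pink_amplitude = pink_amplitude,
                 white_amplitude = white_amplitude,
                 line_freq = line_freq,
                 line_amplitude = line_amplitude),
            class = "noise_spec")
}

#' Sensorimotor rhythm specification
#'
#' The ongoing beta rhythm whose amplitude attenuation constitutes the ERD.
#' By default the rhythm is synthesized as narrowband-filtered noise,
#' independent across channels, with a slow random amplitude modulation —
#' this gives spectral estimates realistic variance. `pure_tone = TRUE`
#' replaces it with a deterministic sine (coherent across channels) for
#' exact-arithmetic oracle tests.
#'
#' @param center_freq center frequency, Hz (> 0).
#' @param bandwidth full bandwidth of the narrowband synthesis, Hz (> 0).
#' @param amplitude RMS amplitude in uV at a channel of weight 1.
#' @param channel_weights named numeric vector of per-channel gains; channels
#'   not named receive weight 0. `NULL` means weight 1 everywhere.
#' @param pure_tone logical; use a deterministic sine instead of narrowband
#'   noise.
#' @param mod_depth relative depth of the slow random amplitude modulation
#'   (ignored in pure-tone mode). The default keeps resting band-power
#'   fluctuations near a coefficient of variation of 0.3, typical of
#'   attentive rest.
#' @return list of class `rhythm_spec`.
#' @export
rhythm_spec <- function(center_freq = 20, bandwidth = 4, amplitude = 3,
                        channel_weights = NULL, pure_tone = FALSE,
                        mod_depth = 0.15) {
  if (center_freq <= 0) stop("center_freq must be > 0", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (!is.null(channel_weights) && any(channel_weights < 0)) {
    stop("channel_weights must be >= 0", call. = FALSE)
  }
  structure(list(center_freq = center_freq, bandwidth = bandwidth,
                 amplitude = amplitude, channel_weights = channel_weights,
                 pure_tone = pure_tone, mod_depth = mod_depth),
            class = "rhythm_spec")
}

#' Default channel weights for lower-limb motor imagery
#'
#' Midline/paracentral emphasis (foot area is near the vertex), tapering
#' laterally.
#' @return named numeric vector over the [default_montage()] channels.
#' @export
default_leg_weights <- function() {
  c(C5 = 0.3, C3 = 0.6, C1 = 0.9, CZ = 1.0, C2 = 0.9, C4 = 0.6)
}

#' ERD event specification
#'
#' One cue or self-paced intent and the ERD episode it elicits: the rhythm
#' amplitude is multiplied by `1 - depth` inside the effective window
#' `[onset + latency, onset + latency + duration)`.
#'
#' @param onset cue or intent time, s (>= 0).
#' @param latency delay from onset to ERD start, s (default 0.5, the typical
#'   lag between a cue and the observable beta suppression).
#' @param duration ERD episode length, s (> 0; default 1, a short imagery
#'   bout).
#' @param depth attenuation in `[0, 1]`; 1 = total rhythm suppression.
#' @param label one of `"cued_move"`, `"cued_rest"`, `"self_paced_intent"`.
#' @return list of class `erd_event`.
#' @export
erd_event <- function(onset, latency = 0.5, duration = 1, depth = 0.6,
                      label = c("cued_move", "cued_rest",
                                "self_paced_intent")) {
  label <- match.arg(label)
  if (onset < 0) stop("onset must be >= 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1]", call. = FALSE)
  structure(list(onset = onset, latency = latency, duration = duration,
                 depth = depth, label = label),
            class = "erd_event")
}

# ---- signal synthesis internals -------------------------------------------
# All stochastic components are drawn from the current RNG stream in a fixed
# order (pink, white, line phase per channel; then rhythm carrier, envelope
# per channel) so a single set.seed() reproduces a session exactly.

pink_noise <- function(n, rms) {
  w <- stats::rnorm(n)
  if (rms == 0) return(numeric(n))
  f <- c(1, seq_len(n - 1))            # pseudo-frequency index; DC removed
  f <- pmin(f, n - f)                  # symmetric for real ifft
  sp <- stats::fft(w) / sqrt(f)
  sp[1] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

narrowband_noise <- function(n, fs, center, bw) {
  w <- stats::rnorm(n)
  edges <- c(max(center - bw / 2, 0.1), min(center + bw / 2, 0.999 * fs / 2))
  bf <- signal::butter(4, edges / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, w)
  x / stats::sd(x)
}

slow_envelope <- function(n, fs, mod_depth) {
  z <- stats::rnorm(n)
  if (mod_depth == 0) return(rep(1, n))
  lf <- signal::butter(2, min(0.5 / (fs / 2), 0.99), type = "low")
  z <- signal::filtfilt(lf, z)
  z <- z / stats::sd(z)
  pmax(1 + mod_depth * z, 0.05)
}

# channels x samples rhythm component at unit event gain
make_rhythm_matrix <- function(n, fs, rhythm, channel_names) {
  wts <- rhythm$channel_weights
  if (is.null(wts)) {
    wts <- stats::setNames(rep(1, length(channel_names)), channel_names)
  }
  unknown <- setdiff(names(wts), channel_names)
  if (length(unknown)) {
    stop("unknown channel label(s) ", paste(unknown, collapse = ", "),
         "; valid labels: ", paste(channel_names, collapse = ", "),
         call. = FALSE)
  }
  gain <- stats::setNames(rep(0, length(channel_names)), channel_names)
  gain[names(wts)] <- wts
  out <- matrix(0, length(channel_names), n)
  if (rhythm$pure_tone) {
    tone <- sqrt(2) * sin(2 * pi * rhythm$center_freq *
                            (seq_len(n) - 1L) / fs)
    for (i in seq_along(channel_names)) {
      out[i, ] <- rhythm$amplitude * gain[i] * tone
    }
  } else {
    for (i in seq_along(channel_names)) {
      carrier <- narrowband_noise(n, fs, rhythm$center_freq, rhythm$bandwidth)
      env <- slow_envelope(n, fs, rhythm$mod_depth)
      x <- carrier * env
      x <- x / stats::sd(x)
      out[i, ] <- rhythm$amplitude * gain[i] * x
    }
  }
  out
}

# ---- operations ------------------------------------------------------------

#' Generate background EEG noise
#'
#' Channels x samples matrix of 1/f plus white (plus optional mains) noise,
#' independent across channels, referenced per the montage.
#'
#' @param duration recording length, s (> 0).
#' @param fs sampling rate, Hz (>= 100).
#' @param montage a [montage_spec()].
#' @param noise a [noise_spec()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return An [eeg_recording()].
#' @export
generate_background <- function(duration, fs = 250,
                                montage = default_montage(),
                                noise = noise_spec(), seed = NULL) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("invalid argument 'duration': must be > 0", call. = FALSE)
  }
  if (!is.numeric(fs) || fs < 100) {
    stop("invalid argument 'fs': must be >= 100 Hz", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * fs)
  ch <- montage$channel_names
  dat <- matrix(0, length(ch), n)
  t <- (seq_len(n) - 1L) / fs
  for (i in seq_along(ch)) {
    dat[i, ] <- dat[i, ] + pink_noise(n, noise$pink_amplitude)
    dat[i, ] <- dat[i, ] + noise$white_amplitude * stats::rnorm(n)
    phase <- stats::runif(1, 0, 2 * pi)
    if (!is.null(noise$line_freq) && noise$line_amplitude > 0) {
      dat[i, ] <- dat[i, ] + noise$line_amplitude * sqrt(2) *
        sin(2 * pi * noise$line_freq * t + phase)
    }
  }
  if (any(dat != 0)) dat <- dat - rowMeans(dat)
  eeg_recording(dat, fs, ch, montage$reference_name)
}

#' Add the sensorimotor rhythm to a recording
#'
#' Purely additive: subtracting the input recovers a narrowband signal
#' concentrated around the rhythm's center frequency.
#'
#' @param recording an [eeg_recording()].
#' @param rhythm a [rhythm_spec()]; `channel_weights` names must be recording
#'   channels.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return An [eeg_recording()].
#' @export
inject_rhythm <- function(recording, rhythm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- make_rhythm_matrix(ncol(recording$data), recording$fs, rhythm,
                          recording$channel_names)
  eeg_recording(recording$data + r, recording$fs, recording$channel_names,
                recording$reference_name)
}

erd_windows <- function(events) {
  data.frame(
    start = vapply(events, function(e) e$onset + e$latency, 0),
    end = vapply(events, function(e) e$onset + e$latency + e$duration, 0),
    depth = vapply(events, function(e) e$depth, 0),
    label = vapply(events, function(e) e$label, "")
  )
}

#' Apply ERD episodes on top of a background recording
#'
#' Adds the rhythm to the background with its amplitude multiplied by
#' `1 - depth` inside each event's effective window
#' `[onset + latency, onset + latency + duration)` and unscaled elsewhere.
#' The returned session's `truth_events` holds one row per event at the
#' cue/intent onset plus one `erd_window` row per attenuated episode with the
#' exact effective window.
#'
#' @param recording the background [eeg_recording()].
#' @param rhythm a [rhythm_spec()].
#' @param events list of [erd_event()] objects; effective windows must be
#'   non-overlapping and inside the recording.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param config optional generator configuration stored with the session.
#' @return A `synthetic_session`: list with `recording`, `truth_events`,
#'   `config`.
#' @export
apply_erd_events <- function(recording, rhythm, events, seed = NULL,
                             config = NULL) {
  stopifnot(all(vapply(events, inherits, TRUE, "erd_event")))
  win <- erd_windows(events)
  dur <- recording_duration(recording)
  if (any(win$end > dur + 1e-9)) {
    bad <- which(win$end > dur + 1e-9)[1]
    stop("event window [", win$start[bad], ", ", win$end[bad],
         ") extends past recording end (", dur, " s)", call. = FALSE)
  }
  if (nrow(win) > 1) {
    o <- order(win$start)
    ws <- win[o, ]
    ov <- which(ws$start[-1] < ws$end[-nrow(ws)])
    if (length(ov)) {
      stop(sprintf(
        "overlapping effective ERD windows: [%g, %g) collides with [%g, %g)",
        ws$start[ov[1]], ws$end[ov[1]], ws$start[ov[1] + 1],
        ws$end[ov[1] + 1]), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- recording$fs
  n <- ncol(recording$data)
  r <- make_rhythm_matrix(n, fs, rhythm, recording$channel_names)
  gain <- rep(1, n)
  for (i in seq_len(nrow(win))) {
    a <- round(win$start[i] * fs) + 1L          # half-open [start, end)
    b <- round(win$end[i] * fs)
    gain[a:b] <- 1 - win$depth[i]
  }
  dat <- recording$data + sweep(r, 2L, gain, `*`)
  ev <- event_list(
    onset = vapply(events, function(e) e$onset, 0),
    duration = vapply(events, function(e) e$duration, 0),
    label = vapply(events, function(e) e$label, "")
  )
  att <- win[win$depth > 0, , drop = FALSE]
  if (nrow(att)) {
    ev <- rbind(ev, event_list(att$start, att$end - att$start,
                               rep("erd_window", nrow(att))))
    ev <- event_list(ev$onset, ev$duration, ev$label)
  }
  structure(
    list(recording = eeg_recording(dat, fs, recording$channel_names,
                                   recording$reference_name),
         truth_events = ev,
         config = config),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("<synthetic_session>\n")
  print(x$recording)
  cat(nrow(x$truth_events), "truth events\n")
  invisible(x)
}
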