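#' ERD percentage
#'
#' Classical convention: percent band-power change relative to a rest
#' reference, `100 * (P - R) / R`. Negative values are desynchronization
#' (power drop); `-100` means complete suppression; positive values are
#' synchronization.
#'
#' @param P event-window band power, uV^2 (>= 0); vectorized.
#' @param R reference (rest) band power, uV^2 (> 0).
#' @return ERD in percent.
#' @export
erd_percent <- function(P, R) {
  if (any(R <= 0)) {
    stop("invalid argument: reference power R must be > 0", call. = FALSE)
  }
  if (any(P < 0)) {
    stop("invalid argument: event power P must be >= 0", call. = FALSE)
  }
  100 * (P - R) / R
}

#' Baseline (rest) band-power statistics
#'
#' Per-channel reference band power from a designated relaxed-rest segment,
#' averaged over analysis windows lying fully inside the source window.
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param band a [freq_band()].
#' @param window `c(start, end)` of the rest segment, seconds.
#' @param window_len,step analysis window length and hop, seconds.
#' @return list of class `baseline_stats`: per-channel `R` (uV^2), `band`,
#'   `source_window`.
#' @export
baseline_stats <- function(recording, band, window,
                           window_len = 0.5, step = 0.125) {
  fs <- recording$fs
  if (window[1] < 0 || window[2] > recording_duration(recording) ||
      window[2] - window[1] < window_len) {
    stop("baseline window must lie inside the recording and be at least one ",
         "analysis window long", call. = FALSE)
  }
  a <- round(window[1] * fs)
  b <- round(window[2] * fs)
  R <- vapply(seq_len(nrow(recording$data)), function(i) {
    bp <- band_power(recording$data[i, (a + 1L):b], fs, band,
                     window_len, step)
    mean(bp$power)
  }, 0)
  names(R) <- recording$channel_names
  if (any(R <= 0)) {
    stop("baseline band power is zero on channel(s) ",
         paste(recording$channel_names[R <= 0], collapse = ", "),
         call. = FALSE)
  }
  structure(list(R = R, band = band, source_window = window),
            class = "baseline_stats")
}

#' Cue-locked time-frequency ERD map
#'
#' For each frequency bin and window position, the ERD% of trial-averaged
#' power against the trial-averaged power in a pre-cue baseline window at
#' the same frequency (averaging over trials, never over frequencies).
#' Channel values are pooled by averaging ERD% across `channels` (default:
#' the midline/paracentral C1, CZ, C2, where lower-limb imagery
#' desynchronizes most).
#'
#' @param epochs an [eeg_epochs()] (cue at time 0).
#' @param baseline_window `c(start, end)` seconds relative to cue; must end
#'   at or before 0 (the baseline must be rest).
#' @param freq_grid frequencies of interest, Hz; snapped to FFT bins.
#' @param window_len analysis window, seconds.
#' @param step hop between windows, seconds.
#' @param channels channel labels to pool (intersected with those present).
#' @return An object of class `tf_map`: `values` (freqs x times matrix of
#'   ERD%), `freqs` (Hz), `times` (s, window centers relative to cue),
#'   `channel` (`"pooled"` or a label). Maps from fewer than 2 trials carry
#'   attribute `low_reliability = TRUE`.
#' @export
erd_time_frequency <- function(epochs, baseline_window = c(-1, 0),
                               freq_grid = seq(8, 30, by = 2),
                               window_len = 0.5, step = 0.125,
                               channels = c("C1", "CZ", "C2")) {
  if (baseline_window[2] > 0) {
    stop("invalid argument: baseline window must end at or before the cue ",
         "(end <= 0)", call. = FALSE)
  }
  if (baseline_window[1] < epochs$tmin) {
    stop("baseline window starts before epoch extent", call. = FALSE)
  }
  fs <- epochs$fs
  n <- round(window_len * fs)
  hop <- round(step * fs)
  n_samp <- dim(epochs$data)[3]
  n_win <- floor((n_samp - n) / hop) + 1L
  starts <- (seq_len(n_win) - 1L) * hop
  times <- epochs$tmin + (starts + n / 2) / fs

  chan_idx <- match(intersect(channels, epochs$channel_names),
                    epochs$channel_names)
  if (!length(chan_idx)) stop("none of the requested channels present",
                              call. = FALSE)
  n_trials <- dim(epochs$data)[1]
  if (n_trials < 1) stop("no trials to map", call. = FALSE)

  freq_all <- (seq_len(floor(n / 2) + 1L) - 1L) * fs / n
  bins <- sort(unique(vapply(freq_grid, function(f) {
    which.min(abs(freq_all - f))
  }, 0L)))
  freqs <- freq_all[bins]

  # baseline windows must lie fully inside the baseline interval
  win_lo <- epochs$tmin + starts / fs
  win_hi <- win_lo + n / fs
  base_cols <- which(win_lo >= baseline_window[1] - 1e-9 &
                       win_hi <= baseline_window[2] + 1e-9)
  if (!length(base_cols)) {
    stop("baseline window shorter than one analysis window", call. = FALSE)
  }

  erd_by_chan <- vapply(chan_idx, function(ci) {
    p <- matrix(0, length(bins), n_win)
    for (k in seq_len(n_trials)) {
      sp <- sliding_psd(epochs$data[k, ci, ], fs, n, starts)
      p <- p + sp$psd[bins, , drop = FALSE]
    }
    p <- p / n_trials
    r <- rowMeans(p[, base_cols, drop = FALSE])
    r[r <= 0] <- .Machine$double.eps
    100 * (p - r) / r
  }, matrix(0, length(bins), n_win))

  values <- apply(erd_by_chan, c(1, 2), mean)
  res <- structure(
    list(values = values, freqs = freqs, times = times,
         channel = if (length(chan_idx) > 1) "pooled" else
           epochs$channel_names[chan_idx]),
    class = "tf_map"
  )
  if (n_trials < 2) attr(res, "low_reliability") <- TRUE
  res
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d freqs x %d times, channel %s, ERD%% range [%.1f, %.1f]\n",
              length(x$freqs), length(x$times), x$channel,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Select the reactive frequency band from an ERD map
#'
#' Returns the contiguous frequency interval of width at least `min_width`
#' that maximizes post-cue desynchronization (most negative mean ERD% over
#' times >= 0). Ties break toward the lower band. When no interval shows net
#' desynchronization the lowest allowed band is returned with attribute
#' `no_reactive_band = TRUE`.
#'
#' @param map a `tf_map` from [erd_time_frequency()].
#' @param search_range a [freq_band()] limiting the search.
#' @param min_width minimum band width, Hz.
#' @return A [freq_band()].
#' @export
select_band <- function(map, search_range = freq_band(8, 30),
                        min_width = 8) {
  if (search_range$high - search_range$low < min_width) {
    stop("invalid argument: search range narrower than min_width",
         call. = FALSE)
  }
  idx <- which(map$freqs >= search_range$low - 1e-9 &
                 map$freqs <= search_range$high + 1e-9)
  if (length(idx) < 2) stop("search range covers fewer than 2 map bins",
                            call. = FALSE)
  post <- which(map$times >= 0)
  if (!length(post)) stop("map has no post-cue time points", call. = FALSE)
  best <- NULL
  best_score <- Inf
  for (i in idx) {
    for (j in idx[idx > i]) {
      if (map$freqs[j] - map$freqs[i] < min_width - 1e-9) next
      rows <- idx[idx >= i & idx <= j]
      score <- mean(map$values[rows, post])
      if (score < best_score - 1e-12) {     # strict: lower band wins ties
        best_score <- score
        best <- c(map$freqs[i], map$freqs[j])
      }
    }
  }
  res <- freq_band(best[1], best[2])
  if (best_score >= 0) attr(res, "no_reactive_band") <- TRUE
  res
}

#' Serialize / read a time-frequency map
#'
#' Self-describing TSV: first column `freq_hz`, remaining columns the window
#' centers (`t<seconds>`), cells ERD%.
#' @param map a `tf_map`.
#' @param path file path.
#' @export
write_tf_map <- function(map, path) {
  header <- paste(c("freq_hz", sprintf("t%.4f", map$times)), collapse = "\t")
  rows <- vapply(seq_along(map$freqs), function(i) {
    paste(c(sprintf("%g", map$freqs[i]),
            sprintf("%.6f", map$values[i, ])), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tf_map
#' @export
read_tf_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "")
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  structure(list(values = as.matrix(df[, -1, drop = FALSE]),
                 freqs = df$freq_hz, times = times, channel = "pooled"),
            class = "tf_map")
}
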