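# Spectral estimation primitives: modified (Hann) periodograms, Welch
# averaging, and vectorized sliding-window band power. Scaling is chosen so
# that summing the one-sided PSD times the bin width recovers signal power
# (a unit-amplitude sine -> 0.5 uV^2).

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * seq_len(n) / n))  # periodic Hann
}

# One-sided modified periodograms of windows of `x` starting at 0-based
# sample offsets `starts`, each `n` samples long. Returns freqs x windows
# PSD matrix (uV^2/Hz) and the frequency grid.
sliding_psd <- function(x, fs, n, starts) {
  w <- hann_window(n)
  idx <- outer(seq_len(n), starts, `+`)
  seg <- matrix(x[idx], nrow = n)
  seg <- sweep(seg, 2L, colMeans(seg))  # per-window demean
  ft <- stats::mvfft(seg * w)
  n_keep <- floor(n / 2) + 1L
  p <- Mod(ft[seq_len(n_keep), , drop = FALSE])^2 / (fs * sum(w^2))
  one_sided <- rep(2, n_keep)
  one_sided[1L] <- 1
  if (n %% 2 == 0) one_sided[n_keep] <- 1
  p <- p * one_sided
  list(freq = (seq_len(n_keep) - 1L) * fs / n, psd = p)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms with Hann windows and 50% overlap.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length in samples (default: `min(length(x), fs)`,
#'   i.e. 1-s segments).
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz, one-sided).
#' @export
welch_psd <- function(x, fs, nperseg = NULL) {
  if (is.null(nperseg)) nperseg <- min(length(x), round(fs))
  nperseg <- as.integer(nperseg)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(0L, length(x) - nperseg, by = step)
  sp <- sliding_psd(x, fs, nperseg, starts)
  list(freq = sp$freq, psd = rowMeans(sp$psd))
}

# Welch band power of sliding analysis windows: within each window of n
# samples starting at the 0-based offsets in `starts`, periodograms of
# sub-segments of length `nperseg` (50% overlap) are averaged, then summed
# over the in-band bins. Sub-segment averaging cuts estimator variance,
# which is what makes single-trial (non-averaged) ERD usable online.
sliding_welch_band_power <- function(x, fs, band, n, starts,
                                     nperseg = NULL) {
  if (is.null(nperseg)) {
    nperseg <- if (n >= 32) max(8L, ceiling(n / 2)) else n
  }
  nperseg <- min(nperseg, n)
  hop <- max(1L, nperseg %/% 2L)
  offsets <- seq(0L, n - nperseg, by = hop)
  sub_starts <- as.vector(outer(offsets, starts, `+`))
  sp <- sliding_psd(x, fs, nperseg, sub_starts)
  bp <- psd_band_power(sp, band)
  colMeans(matrix(bp, nrow = length(offsets)))
}

# Band power from a PSD matrix: sum of in-band bins times bin width. Each
# bin covers [f - df/2, f + df/2), so bins straddling an edge count when
# their center lies within half a bin of the band.
psd_band_power <- function(sp, band) {
  df_half <- (sp$freq[2L] - sp$freq[1L]) / 2
  sel <- sp$freq >= band$low - df_half & sp$freq < band$high + df_half
  if (!any(sel)) stop("no PSD bins inside band [", band$low, ", ", band$high,
                      "] Hz", call. = FALSE)
  df <- sp$freq[2L] - sp$freq[1L]
  colSums(sp$psd[sel, , drop = FALSE]) * df
}

#' Frequency band
#'
#' @param low,high band edges in Hz, `0 < low < high`.
#' @return list of class `freq_band`.
#' @export
freq_band <- function(low, high) {
  if (!(low > 0 && high > low)) {
    stop("band requires 0 < low < high, got [", low, ", ", high, "]",
         call. = FALSE)
  }
  structure(list(low = low, high = high), class = "freq_band")
}

#' Sliding-window band power
#'
#' Band power (uV^2) of a single-channel series in consecutive analysis
#' windows, estimated from a Hann-windowed periodogram per window. Output
#' timestamps are window centers; the series has
#' `floor((T - window_len)/step) + 1` points.
#'
#' @param x single-channel numeric series, microvolts.
#' @param fs sampling rate, Hz.
#' @param band a [freq_band()]; `band$high` must be below `fs/2`.
#' @param window_len analysis window length, seconds (`window_len * fs >= 8`).
#' @param step hop between windows, seconds.
#' @return list with `time` (window centers, s) and `power` (uV^2).
#' @export
band_power <- function(x, fs, band, window_len = 0.5, step = 0.125) {
  if (band$high >= fs / 2) {
    stop("band.high (", band$high, " Hz) must be below Nyquist (", fs / 2,
         " Hz)", call. = FALSE)
  }
  n <- round(window_len * fs)
  if (n < 8) stop("window_len * fs must be >= 8 samples", call. = FALSE)
  hop <- round(step * fs)
  if (hop < 1) stop("step too small for sampling rate", call. = FALSE)
  n_win <- floor((length(x) - n) / hop) + 1L
  if (n_win < 1L) return(list(time = numeric(), power = numeric()))
  starts <- (seq_len(n_win) - 1L) * hop
  list(time = (starts + n / 2) / fs,
       power = sliding_welch_band_power(x, fs, band, n, starts))
}
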