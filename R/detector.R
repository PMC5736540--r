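#' Online detector configuration
#'
#' @param threshold decision threshold: on the LDA score in `lda_score` mode
#'   (fires when score >= threshold), on pooled ERD% in `raw_erd` mode
#'   (fires when ERD% <= threshold, desynchronization being negative).
#' @param dwell minimum continuous supra-threshold time before a detection
#'   fires, seconds (>= 0). The default (1 s) spans most of the ~1.5 s
#'   imagery bout, so sustained intentional ERD passes while shorter
#'   spontaneous beta-power dips do not.
#' @param refractory lockout after a detection, seconds (>= 0). Blocks
#'   double-triggers within one stride.
#' @param window_len,step analysis window length and update step, seconds.
#' @param mode `"lda_score"` or `"raw_erd"`.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(threshold = 0, dwell = 1, refractory = 3,
                            window_len = 0.5, step = 0.125,
                            mode = c("lda_score", "raw_erd")) {
  mode <- match.arg(mode)
  if (dwell < 0) stop("dwell must be >= 0", call. = FALSE)
  if (refractory < 0) stop("refractory must be >= 0", call. = FALSE)
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  structure(list(threshold = threshold, dwell = dwell,
                 refractory = refractory, window_len = window_len,
                 step = step, mode = mode),
            class = "detector_config")
}

#' Causal feature extraction
#'
#' Per-channel log band power (log uV^2) in the selected band over sliding
#' analysis windows. Each window uses only samples up to its end time
#' (causal); the series stops at the last full window. When `baseline` is
#' supplied, the pooled single-window ERD% against the per-channel reference
#' power is also returned (mean across channels) — the raw-ERD online path,
#' computed per window without trial back-averaging.
#'
#' @param recording a preprocessed [eeg_recording()].
#' @param band a [freq_band()].
#' @param window_len,step window length and hop, seconds.
#' @param baseline optional [baseline_stats()]; required for `raw_erd` mode.
#' @param mode `"lda_score"` or `"raw_erd"`.
#' @param skip_initial discard windows containing samples earlier than this
#'   time, seconds (filter warm-up; online paths use 1 s).
#' @return list of class `feature_series`: `times` (window ends, s),
#'   `features` (windows x channels log band power), `pooled_erd`
#'   (windows, %; only with a baseline), `band`, `mode`.
#' @export
extract_features <- function(recording, band, window_len = 0.5,
                             step = 0.125, baseline = NULL,
                             mode = c("lda_score", "raw_erd"),
                             skip_initial = 0) {
  mode <- match.arg(mode)
  if (mode == "raw_erd" && is.null(baseline)) {
    stop("configuration error: raw_erd mode requires baseline stats",
         call. = FALSE)
  }
  fs <- recording$fs
  n <- round(window_len * fs)
  hop <- round(step * fs)
  n_win <- floor((ncol(recording$data) - n) / hop) + 1L
  if (n_win < 1L) {
    return(structure(list(times = numeric(),
                          features = matrix(0, 0, nrow(recording$data)),
                          pooled_erd = numeric(), band = band, mode = mode),
                     class = "feature_series"))
  }
  starts <- (seq_len(n_win) - 1L) * hop
  starts <- starts[starts / fs >= skip_initial - 1e-9]
  if (!length(starts)) {
    return(structure(list(times = numeric(),
                          features = matrix(0, 0, nrow(recording$data)),
                          pooled_erd = NULL, band = band, mode = mode),
                     class = "feature_series"))
  }
  n_win <- length(starts)
  pow <- vapply(seq_len(nrow(recording$data)), function(i) {
    sliding_welch_band_power(recording$data[i, ], fs, band, n, starts)
  }, numeric(n_win))
  pow <- matrix(pow, nrow = n_win)
  colnames(pow) <- recording$channel_names
  res <- list(times = (starts + n) / fs,
              features = log(pmax(pow, .Machine$double.xmin)),
              pooled_erd = NULL, band = band, mode = mode)
  if (!is.null(baseline)) {
    erd <- sweep(sweep(pow, 2L, baseline$R, `/`) - 1, 1L, 100, `*`)
    res$pooled_erd <- rowMeans(erd)
  }
  structure(res, class = "feature_series")
}

# dwell/refractory threshold scan over a causal decision series.
# supra: logical vector; returns indices where detections fire.
dwell_scan <- function(times, supra, dwell, refractory) {
  fired <- integer()
  run_start <- NA_real_
  last_fire <- -Inf
  for (i in seq_along(times)) {
    if (times[i] < last_fire + refractory) {
      run_start <- NA_real_
      next
    }
    if (supra[i]) {
      if (is.na(run_start)) run_start <- times[i]
      if (times[i] - run_start >= dwell) {
        fired <- c(fired, i)
        last_fire <- times[i]
        run_start <- NA_real_
      }
    } else {
      run_start <- NA_real_
    }
  }
  fired
}

#' Run the self-paced online detector
#'
#' Scans a causal decision series and fires a detection the first time the
#' statistic has been past threshold continuously for at least `dwell`
#' seconds; after a detection no further detection can fire for `refractory`
#' seconds. `lda_score` mode triggers on score >= threshold; `raw_erd` mode
#' on pooled ERD% <= threshold.
#'
#' @param features a [extract_features()] series (time-ordered).
#' @param model an `lda_model` (required in `lda_score` mode).
#' @param config a [detector_config()].
#' @return data frame of class `detection_events` with columns `time`,
#'   `score`, `mode`.
#' @export
detect_online <- function(features, model = NULL, config) {
  times <- features$times
  if (is.unsorted(times, strictly = TRUE)) {
    stop("feature stream times must be strictly increasing", call. = FALSE)
  }
  if (config$mode == "lda_score") {
    if (is.null(model)) stop("lda_score mode requires a model", call. = FALSE)
    stat <- lda_score(model, features$features)
    supra <- stat >= config$threshold
  } else {
    if (is.null(features$pooled_erd)) {
      stop("configuration error: raw_erd mode requires features extracted ",
           "with baseline stats", call. = FALSE)
    }
    stat <- features$pooled_erd
    supra <- stat <= config$threshold
  }
  idx <- dwell_scan(times, supra, config$dwell, config$refractory)
  out <- data.frame(time = times[idx], score = stat[idx],
                    mode = rep(config$mode, length(idx)))
  class(out) <- c("detection_events", "data.frame")
  out
}

#' Calibrate the detection threshold on rest data
#'
#' Returns the least extreme threshold whose dwell-filtered false-trigger
#' rate on a detection-free rest series does not exceed the target,
#' conservative on ties. When even the most extreme observed score triggers
#' too often, a threshold strictly past the extreme is returned.
#'
#' @param rest_scores list with `times` (s) and `values`: the decision
#'   statistic on rest data (LDA scores, or pooled ERD% in raw mode).
#' @param target_false_rate tolerated false triggers per minute (default 0).
#' @param config a [detector_config()] supplying dwell, refractory and mode.
#' @return numeric threshold on the scale of the decision statistic.
#' @export
calibrate_threshold <- function(rest_scores, target_false_rate = 0,
                                config = detector_config()) {
  times <- rest_scores$times
  x <- rest_scores$values
  if (length(times) < 2 || diff(range(times)) < 60) {
    stop("rest data must span at least 60 s of detection-free baseline",
         call. = FALSE)
  }
  minutes <- diff(range(times)) / 60
  # work in the ">= threshold fires" orientation; mirror for raw ERD
  flip <- config$mode == "raw_erd"
  s <- if (flip) -x else x
  rate_at <- function(thr) {
    length(dwell_scan(times, s >= thr, config$dwell, config$refractory)) /
      minutes
  }
  cand <- sort(unique(s))
  # rate is (essentially) nonincreasing in thr: binary search the boundary,
  # then verify and walk upward if needed
  lo <- 1L
  hi <- length(cand)
  if (rate_at(cand[hi]) <= target_false_rate) {
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (rate_at(cand[mid]) <= target_false_rate) hi <- mid else lo <- mid + 1L
    }
    idx <- hi
    while (idx <= length(cand) && rate_at(cand[idx]) > target_false_rate) {
      idx <- idx + 1L
    }
    if (idx <= length(cand)) {
      thr <- cand[idx]
      return(if (flip) -thr else thr)
    }
  }
  margin <- max(1e-8, 1e-6 * max(abs(cand)), 1e-9 * diff(range(cand)))
  thr <- cand[length(cand)] + margin
  if (flip) -thr else thr
}
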