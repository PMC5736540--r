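#' Labeled training features from a cued session
#'
#' Extracts causal per-channel log band-power features over the whole
#' preprocessed recording, then keeps the windows lying fully inside each
#' cue's imagery interval `onset + imagery_window`, labeled by the cue. Each
#' window is one training example (the online detector sees exactly these
#' statistics).
#'
#' @param recording preprocessed [eeg_recording()].
#' @param events [event_list()] with `cued_move` / `cued_rest` rows.
#' @param band a [freq_band()].
#' @param imagery_window `c(start, end)` seconds relative to cue; default
#'   `c(0.5, 1.5)` — ERD starts about 0.5 s after the cue and imagery is
#'   held for about 1 s.
#' @param window_len,step analysis window and hop, seconds.
#' @return list: `features` (windows x channels), `labels`, `trial` (cue
#'   index per window).
#' @export
training_features <- function(recording, events, band,
                              imagery_window = c(0.5, 1.5),
                              window_len = 0.5, step = 0.125) {
  cues <- events[events$label %in% c("cued_move", "cued_rest"), ,
                 drop = FALSE]
  if (!nrow(cues)) stop("no cued events in session", call. = FALSE)
  fs <- recording$fs
  feats <- extract_features(recording, band, window_len, step)
  w_start <- feats$times - window_len
  keep <- integer()
  labels <- character()
  trial <- integer()
  centers <- (w_start + feats$times) / 2
  for (k in seq_len(nrow(cues))) {
    lo <- cues$onset[k] + imagery_window[1]
    hi <- cues$onset[k] + imagery_window[2]
    sel <- which(centers >= lo - 1e-9 & centers <= hi + 1e-9)
    keep <- c(keep, sel)
    labels <- c(labels, rep(cues$label[k], length(sel)))
    trial <- c(trial, rep(k, length(sel)))
  }
  list(features = feats$features[keep, , drop = FALSE], labels = labels,
       trial = trial)
}

#' Train the intent model from a cued training session
#'
#' Offline path: zero-phase 1-100 Hz bandpass, small-Laplacian, cue-locked
#' ERD time-frequency map, data-driven reactive-band selection (unless a
#' band is given), then shrinkage LDA on log band-power features from the
#' imagery windows (move) and the same windows of rest trials.
#'
#' @param session a `synthetic_session` from the `cued_training` preset (or
#'   any session with cued events).
#' @param band fixed [freq_band()], or `NULL` to select from the ERD map.
#' @param shrinkage LDA shrinkage in `[0, 1]`.
#' @param window_len,step analysis window and hop, seconds.
#' @param imagery_window feature interval relative to cue, seconds.
#' @return An `lda_model` with the selected `band` and the training `tf_map`
#'   attached.
#' @export
train_intent_model <- function(session, band = NULL, shrinkage = 0.1,
                               window_len = 0.5, step = 0.125,
                               imagery_window = c(0.5, 1.5)) {
  proc <- bandpass(session$recording,
                   filter_spec(1, 100, mode = "zero_phase_offline"))
  proc <- laplacian(proc)
  map <- NULL
  if (is.null(band)) {
    ep <- epoch(proc, session$truth_events, tmin = -1.5, tmax = 2.5,
                labels_filter = "cued_move")
    # the map keeps its own 0.5 s window: band selection needs 2 Hz bins
    map <- erd_time_frequency(ep, baseline_window = c(-1, 0),
                              freq_grid = seq(6, 34, by = 2),
                              window_len = 0.5, step = step)
    band <- select_band(map, freq_band(8, 30), min_width = 8)
  }
  tf <- training_features(proc, session$truth_events, band,
                          imagery_window, window_len, step)
  model <- fit_lda(tf$features, tf$labels, positive_class = "cued_move",
                   shrinkage = shrinkage)
  model$band <- band
  model$tf_map <- map
  model
}

#' Calibrate the unlock threshold on a session's rest segment
#'
#' Computes the decision statistic over the session's designated relaxed
#' baseline segment (causal preprocessing, same features as the online
#' detector) and returns the least extreme threshold meeting the target
#' false-trigger rate.
#'
#' @param session a self-paced `synthetic_session` with a baseline window.
#' @param model an `lda_model` (ignored in `raw_erd` mode).
#' @param det_cfg a [detector_config()].
#' @param target_false_rate tolerated false triggers per minute.
#' @param margin_sd safety margin added in the conservative direction, in
#'   units of the rest-statistic standard deviation. A threshold meeting the
#'   target exactly on a finite rest sample sits at the sample's edge; the
#'   margin buys false-positive headroom on unseen data at a small cost in
#'   sensitivity (spontaneous stance-phase unlocks are the clinically
#'   dangerous failure).
#' @return numeric threshold.
#' @export
calibrate_on_session <- function(session, model, det_cfg,
                                 target_false_rate = 0, margin_sd = 0.375) {
  bw <- session$baseline_window
  if (is.null(bw)) stop("session has no designated baseline window",
                        call. = FALSE)
  band <- if (!is.null(model$band)) model$band else freq_band(16, 24)
  proc <- bandpass(session$recording,
                   filter_spec(1, 100, mode = "causal_online"))
  proc <- laplacian(proc)
  a <- round(bw[1] * proc$fs) + 1L
  b <- round(bw[2] * proc$fs)
  rest <- eeg_recording(proc$data[, a:b, drop = FALSE], proc$fs,
                        proc$channel_names, proc$reference_name)
  baseline <- if (det_cfg$mode == "raw_erd") {
    baseline_stats(rest, band, c(0, bw[2] - bw[1]), det_cfg$window_len,
                   det_cfg$step)
  } else NULL
  feats <- extract_features(rest, band, det_cfg$window_len, det_cfg$step,
                            baseline = baseline, mode = det_cfg$mode,
                            skip_initial = 1)
  values <- if (det_cfg$mode == "lda_score") {
    lda_score(model, feats$features)
  } else {
    feats$pooled_erd
  }
  thr <- calibrate_threshold(list(times = feats$times, values = values),
                             target_false_rate, det_cfg)
  if (det_cfg$mode == "lda_score") {
    thr + margin_sd * stats::sd(values)
  } else {
    thr - margin_sd * stats::sd(values)
  }
}

#' Run the full simulate-train-calibrate-closed-loop chain
#'
#' Generates a cued training session and a self-paced walking session,
#' trains the intent model (with reactive-band selection), calibrates the
#' unlock threshold on the walking session's opening rest segment, runs the
#' closed loop, and writes every artifact (sessions, model, ERD map, trace,
#' report) under `out_dir`. Fully deterministic for fixed `(config, seed)`.
#'
#' @param config configuration list (or path to a YAML file) with optional
#'   entries `seed`, `band` (`"auto"` or `c(low, high)`), `detector`
#'   (arguments of [detector_config()] plus `target_false_rate`), `train`
#'   and `test` ([session_config()] argument lists).
#' @param out_dir output directory.
#' @param seed overrides `config$seed`.
#' @return list (invisible): `model`, `threshold`, `trace`, `summary`,
#'   `out_dir`.
#' @export
run_all <- function(config = list(), out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  train_args <- config$train
  train_args$preset <- "cued_training"
  test_args <- config$test
  test_args$preset <- "self_paced_walk"
  train_cfg <- do.call(session_config, train_args)
  test_cfg <- do.call(session_config, test_args)

  det_args <- config$detector
  target <- if (!is.null(det_args$target_false_rate)) {
    det_args$target_false_rate
  } else 0
  det_args$target_false_rate <- NULL
  det_cfg <- do.call(detector_config, det_args)

  band <- NULL
  if (!is.null(config$band) && !identical(config$band, "auto")) {
    band <- freq_band(config$band[[1]], config$band[[2]])
  }

  train_session <- generate_session(train_cfg, seed)
  test_session <- generate_session(test_cfg, seed + 1L)
  write_session(train_session, file.path(out_dir, "train_session"))
  write_session(test_session, file.path(out_dir, "test_session"))

  model <- train_intent_model(train_session, band = band,
                              window_len = det_cfg$window_len,
                              step = det_cfg$step)
  write_lda_model(model, file.path(out_dir, "model.txt"))
  if (!is.null(model$tf_map)) {
    write_tf_map(model$tf_map, file.path(out_dir, "tf_map.tsv"))
  }

  det_cfg$threshold <- calibrate_on_session(test_session, model, det_cfg,
                                            target)
  writeLines(sprintf("threshold: %.17g", det_cfg$threshold),
             file.path(out_dir, "threshold.txt"))

  trace <- run_closed_loop(test_session, model, det_cfg)
  write_trace(trace, file.path(out_dir, "trace"))
  summary <- session_summary(trace)
  write_report(summary, file.path(out_dir, "report.tsv"))

  invisible(list(model = model, threshold = det_cfg$threshold,
                 trace = trace, summary = summary, out_dir = out_dir))
}
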