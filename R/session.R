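#' Generator configuration
#'
#' Full parameter set for [generate_session()]. Defaults are the package's
#' "clinic" study conditions: 250 Hz sampling, the six-channel motor-strip
#' montage referenced to CZA, a 20 Hz beta rhythm (16-24 Hz band) of 3 uV RMS
#' with midline-weighted topography, 1/f-dominated background noise, ERD
#' starting 0.5 s after each cue/intent.
#'
#' @param preset `"cued_training"` (alternating cued move/rest trials) or
#'   `"self_paced_walk"` (scripted gait with self-paced intents and no
#'   inter-trial structure).
#' @param fs sampling rate, Hz (100-1000).
#' @param noise,rhythm parameter lists overriding [noise_spec()] /
#'   [rhythm_spec()] defaults.
#' @param erd list: `latency` (s), `duration` (s), `depth` in `[0,1]`.
#' @param cued list for the cued preset: `n_trials`, `trial_interval` (s),
#'   `first_cue` (s).
#' @param walk list for the self-paced preset: `n_segments`,
#'   `attempts_per_segment`, `baseline_duration` (opening relaxed-rest
#'   segment, s), `stand_up`, `stance`, `swing`, `sit` phase durations (s),
#'   `intent_delay` (s from swing-phase start to intent), `include_sit`.
#' @return list of class `session_config`.
#' @export
session_config <- function(preset = c("cued_training", "self_paced_walk"),
                           fs = 250, noise = list(), rhythm = list(),
                           erd = list(), cued = list(), walk = list()) {
  preset <- match.arg(preset)
  defaults <- list(
    erd = list(latency = 0.5, duration = 1, depth = 0.6),
    cued = list(n_trials = 20, trial_interval = 4, first_cue = 3),
    walk = list(n_segments = 2, attempts_per_segment = 4,
                baseline_duration = 62.5, stand_up = 2, stance = 2.5,
                swing = 4, sit = 4, intent_delay = 0.5, include_sit = TRUE)
  )
  check_fields <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown config field '", where, ".", bad[1], "'", call. = FALSE)
    }
  }
  check_fields(noise, names(formals(noise_spec)), "noise")
  check_fields(rhythm, names(formals(rhythm_spec)), "rhythm")
  check_fields(erd, names(defaults$erd), "erd")
  check_fields(cued, names(defaults$cued), "cued")
  check_fields(walk, names(defaults$walk), "walk")
  if (!is.numeric(fs) || fs < 100 || fs > 1000) {
    stop("unknown or invalid config field 'fs': must be in [100, 1000] Hz",
         call. = FALSE)
  }
  if (preset == "self_paced_walk") {
    defaults$erd$duration <- 1.5
  }
  merge <- function(d, o) { d[names(o)] <- o; d }
  structure(
    list(preset = preset, fs = fs,
         noise = noise, rhythm = rhythm,
         erd = merge(defaults$erd, erd),
         cued = merge(defaults$cued, cued),
         walk = merge(defaults$walk, walk)),
    class = "session_config"
  )
}

build_rhythm <- function(config) {
  args <- config$rhythm
  if (is.null(args$channel_weights)) {
    args$channel_weights <- default_leg_weights()
  } else {
    args$channel_weights <- unlist(args$channel_weights)
  }
  do.call(rhythm_spec, args)
}

build_gait_script <- function(walk) {
  rows <- list()
  t <- 0
  attempt <- 0L
  add <- function(kind, dur, seg, att = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start = t, duration = dur, kind = kind, segment_id = seg,
      attempt_id = att)
    t <<- t + dur
  }
  add("rest", walk$baseline_duration, 0L)
  add("stand_up", walk$stand_up, 0L)
  for (seg in seq_len(walk$n_segments)) {
    for (a in seq_len(walk$attempts_per_segment)) {
      add("stance", walk$stance, seg)
      attempt <- attempt + 1L
      add("swing_attempt", walk$swing, seg, attempt)
    }
    add("stance", walk$stance, seg)
  }
  if (isTRUE(walk$include_sit)) {
    attempt <- attempt + 1L
    add("sit_attempt", walk$sit, walk$n_segments + 1L, attempt)
    add("rest", 2, walk$n_segments + 1L)
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic session
#'
#' Composes background noise, the beta rhythm, and ERD episodes according to
#' a [session_config()]. The `cued_training` preset alternates `cued_move`
#' and `cued_rest` trials at fixed intervals (ERD only on move trials); the
#' `self_paced_walk` preset couples `self_paced_intent` events to the
#' swing/sit attempts of a generated gait script, with no inter-trial breaks.
#' A single RNG stream seeded once drives every stochastic component, so the
#' same `(config, seed)` reproduces the session exactly.
#'
#' @param config a [session_config()].
#' @param seed integer seed.
#' @return A `synthetic_session` with `recording`, `truth_events`, `config`
#'   (including the seed), and — for the self-paced preset — `gait_script`
#'   and `baseline_window`.
#' @export
generate_session <- function(config, seed = 1L) {
  if (!inherits(config, "session_config")) {
    stop("config must be a session_config object", call. = FALSE)
  }
  montage <- default_montage()
  noise <- do.call(noise_spec, config$noise)
  rhythm <- build_rhythm(config)
  erd <- config$erd
  gait <- NULL

  if (config$preset == "cued_training") {
    p <- config$cued
    onsets <- p$first_cue + (seq_len(p$n_trials) - 1L) * p$trial_interval
    labels <- rep(c("cued_move", "cued_rest"), length.out = p$n_trials)
    events <- Map(function(t0, lab) {
      erd_event(t0, latency = erd$latency, duration = erd$duration,
                depth = if (lab == "cued_move") erd$depth else 0,
                label = lab)
    }, onsets, labels)
    duration <- max(onsets) + p$trial_interval + 2
    baseline_window <- NULL
  } else {
    gait <- build_gait_script(config$walk)
    attempts <- gait[gait$kind %in% c("swing_attempt", "sit_attempt"), ]
    events <- Map(function(t0) {
      erd_event(t0, latency = erd$latency, duration = erd$duration,
                depth = erd$depth, label = "self_paced_intent")
    }, attempts$start + config$walk$intent_delay)
    duration <- max(gait$start + gait$duration) + 1
    baseline_window <- c(0, config$walk$baseline_duration)
  }

  set.seed(seed)
  bg <- generate_background(duration, config$fs, montage, noise, seed = NULL)
  full_config <- unclass(config)
  full_config$seed <- seed
  session <- apply_erd_events(bg, rhythm, events, seed = NULL,
                              config = full_config)
  session$gait_script <- gait
  session$baseline_window <- baseline_window
  session
}

#' Write / read a session directory
#'
#' A session directory holds `recording.edf` (signals, uV),
#' `events.tsv` (truth events), `config.yaml` (full generator configuration
#' including the seed) and, for self-paced sessions, `gait_script.tsv`
#' (`start  duration  kind  segment_id  attempt_id`).
#'
#' @param session a `synthetic_session`.
#' @param dir directory path (created if missing).
#' @return `write_session` returns `dir` invisibly; `read_session` returns
#'   the reconstructed session (recording values carry EDF quantization).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(session$recording, file.path(dir, "recording.edf"))
  write_events(session$truth_events, file.path(dir, "events.tsv"))
  if (!is.null(session$config)) {
    yaml::write_yaml(session$config, file.path(dir, "config.yaml"))
  }
  if (!is.null(session$gait_script)) {
    write_gait_script(session$gait_script, file.path(dir, "gait_script.tsv"))
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  recording <- read_edf(file.path(dir, "recording.edf"))
  events <- read_events(file.path(dir, "events.tsv"))
  cfg_path <- file.path(dir, "config.yaml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  gait_path <- file.path(dir, "gait_script.tsv")
  gait <- if (file.exists(gait_path)) read_gait_script(gait_path) else NULL
  baseline <- NULL
  if (!is.null(config) && identical(config$preset, "self_paced_walk")) {
    baseline <- c(0, config$walk$baseline_duration)
  }
  structure(list(recording = recording, truth_events = events,
                 config = config, gait_script = gait,
                 baseline_window = baseline),
            class = "synthetic_session")
}

#' Write / read a gait script
#'
#' Tab-separated with columns `start`, `duration`, `kind`, `segment_id`,
#' `attempt_id`.
#' @param script gait script data frame.
#' @param path file path.
#' @export
write_gait_script <- function(script, path) {
  df <- script
  df$start <- sprintf("%.6f", df$start)
  df$duration <- sprintf("%.6f", df$duration)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("start\tduration\tkind\tsegment_id\tattempt_id",
               paste(df$start, df$duration, df$kind, df$segment_id,
                     df$attempt_id, sep = "\t")),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gait_script
#' @export
read_gait_script <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "",
                    na.strings = "NA")
}
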