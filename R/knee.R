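#' Prosthetic knee-lock state
#'
#' @param state `"LOCKED"` or `"UNLOCKED"`.
#' @param since time the state was entered, seconds.
#' @return list of class `knee_state`.
#' @export
knee_state <- function(state = "LOCKED", since = 0) {
  state <- match.arg(state, c("LOCKED", "UNLOCKED"))
  structure(list(state = state, since = since), class = "knee_state")
}

#' Knee-lock state transition
#'
#' The brain switch unlocks; extending the knee (a scripted action of the
#' wearer) re-locks. All other (state, event) pairs are no-ops, flagged
#' redundant on the returned state — robustness over strictness in closed
#' loop.
#'
#' @param state a [knee_state()].
#' @param event `"bci_unlock"` or `"knee_extension"`.
#' @param time event time, seconds; must not precede `state$since`.
#' @return The new [knee_state()]; attribute `redundant` is `TRUE` for
#'   no-op events.
#' @export
knee_step <- function(state, event, time) {
  event <- match.arg(event, c("bci_unlock", "knee_extension"))
  if (time < state$since) {
    stop("time regression: event at ", time, " s precedes state since ",
         state$since, " s", call. = FALSE)
  }
  if (state$state == "LOCKED" && event == "bci_unlock") {
    return(knee_state("UNLOCKED", time))
  }
  if (state$state == "UNLOCKED" && event == "knee_extension") {
    return(knee_state("LOCKED", time))
  }
  out <- knee_state(state$state, state$since)
  attr(out, "redundant") <- TRUE
  out
}

# replay a time-ordered event table through knee_step, returning the
# timeline (one row per event with states before/after and redundancy flag)
replay_knee <- function(events_df, initial = knee_state("LOCKED", 0)) {
  st <- initial
  n <- nrow(events_df)
  before <- character(n)
  after <- character(n)
  redundant <- logical(n)
  for (i in seq_len(n)) {
    before[i] <- st$state
    st <- knee_step(st, events_df$event[i], events_df$time[i])
    after[i] <- st$state
    redundant[i] <- isTRUE(attr(st, "redundant"))
  }
  cbind(events_df, data.frame(state_before = before, state_after = after,
                              redundant = redundant))
}

#' Run the closed-loop brain-switch trial
#'
#' The in-silico analogue of the parallel-bars trial: the detector runs
#' causally over the whole session; each detection issues a `bci_unlock`
#' event; a scripted `knee_extension` re-locks the knee at the end of every
#' swing/sit attempt phase. An attempt is a first-try success iff a
#' detection unlocks the knee inside its phase window at or after its first
#' intent.
#'
#' @param session a `synthetic_session` (self-paced preset).
#' @param model an `lda_model`, or `NULL` in `raw_erd` mode.
#' @param det_cfg a [detector_config()].
#' @param script gait script data frame; defaults to the session's own.
#' @param band analysis [freq_band()]; defaults to the model's stored band,
#'   else 16-24 Hz.
#' @param baseline optional [baseline_stats()] for `raw_erd` mode; computed
#'   from the session's opening rest segment when absent.
#' @return list of class `session_trace`: `timeline` (replayed knee events),
#'   `detections`, `script`, `outcomes` (one row per attempt:
#'   `attempt_id`, `segment_id`, `kind`, `intent_onset`,
#'   `first_try_success`, `n_detections`, `latency`), `truth_events`.
#' @export
run_closed_loop <- function(session, model, det_cfg, script = NULL,
                            band = NULL, baseline = NULL) {
  if (is.null(script)) script <- session$gait_script
  if (is.null(script)) stop("no gait script available", call. = FALSE)
  dur <- recording_duration(session$recording)
  if (max(script$start + script$duration) > dur + 1e-9) {
    stop("gait script extends past the recording (", dur, " s)",
         call. = FALSE)
  }
  if (is.null(band)) {
    band <- if (!is.null(model$band)) model$band else freq_band(16, 24)
  }

  proc <- bandpass(session$recording,
                   filter_spec(1, 100, mode = "causal_online"))
  proc <- laplacian(proc)
  if (det_cfg$mode == "raw_erd" && is.null(baseline)) {
    if (is.null(session$baseline_window)) {
      stop("raw_erd mode needs a baseline window or baseline stats",
           call. = FALSE)
    }
    baseline <- baseline_stats(proc, band, session$baseline_window,
                               det_cfg$window_len, det_cfg$step)
  }
  feats <- extract_features(proc, band, det_cfg$window_len, det_cfg$step,
                            baseline = baseline, mode = det_cfg$mode,
                            skip_initial = 1)
  detections <- detect_online(feats, model, det_cfg)

  attempts <- script[script$kind %in% c("swing_attempt", "sit_attempt"), ,
                     drop = FALSE]
  relock <- data.frame(time = attempts$start + attempts$duration,
                       event = rep("knee_extension", nrow(attempts)))
  unlocks <- data.frame(time = detections$time,
                        event = rep("bci_unlock", nrow(detections)))
  evs <- rbind(unlocks, relock)
  evs <- evs[order(evs$time, evs$event), , drop = FALSE]  # unlock before re-lock at ties
  rownames(evs) <- NULL
  timeline <- replay_knee(evs)

  truth <- session$truth_events
  intents <- truth[truth$label == "self_paced_intent", , drop = FALSE]
  unlock_times <- timeline$time[timeline$event == "bci_unlock" &
                                  !timeline$redundant]
  outcomes <- do.call(rbind, lapply(seq_len(nrow(attempts)), function(k) {
    a <- attempts[k, ]
    lo <- a$start
    hi <- a$start + a$duration
    ints <- intents$onset[intents$onset >= lo - 1e-9 &
                            intents$onset < hi - 1e-9]
    t_int <- if (length(ints)) min(ints) else NA_real_
    in_phase <- detections$time[detections$time >= lo &
                                  detections$time < hi]
    hit <- if (is.na(t_int)) numeric() else
      unlock_times[unlock_times >= t_int & unlock_times < hi]
    success <- length(hit) > 0
    data.frame(attempt_id = a$attempt_id, segment_id = a$segment_id,
               kind = a$kind, intent_onset = t_int,
               first_try_success = success,
               n_detections = length(in_phase),
               latency = if (success) min(hit) - t_int else NA_real_)
  }))
  rownames(outcomes) <- NULL
  structure(list(timeline = timeline, detections = detections,
                 script = script, outcomes = outcomes,
                 truth_events = truth),
            class = "session_trace")
}

#' @export
print.session_trace <- function(x, ...) {
  cat(sprintf("<session_trace> %d detections, %d attempts (%d first-try successes)\n",
              nrow(x$detections), nrow(x$outcomes),
              sum(x$outcomes$first_try_success)))
  invisible(x)
}

#' Write a session trace to a directory
#'
#' `trace_events.tsv` holds the merged knee/detection timeline;
#' `outcomes.tsv` the per-attempt outcomes; `gait_script.tsv` the script.
#' @param trace a `session_trace`.
#' @param dir output directory.
#' @export
write_trace <- function(trace, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tl <- trace$timeline
  tl$time <- sprintf("%.6f", tl$time)
  write_tsv_raw(tl, file.path(dir, "trace_events.tsv"))
  oc <- trace$outcomes
  oc$intent_onset <- sprintf("%.6f", oc$intent_onset)
  oc$latency <- ifelse(is.na(trace$outcomes$latency), "NA",
                       sprintf("%.6f", trace$outcomes$latency))
  write_tsv_raw(oc, file.path(dir, "outcomes.tsv"))
  write_gait_script(trace$script, file.path(dir, "gait_script.tsv"))
  write_events(trace$truth_events, file.path(dir, "truth_events.tsv"))
  invisible(dir)
}

#' Read a session trace directory written by [write_trace()]
#' @param dir trace directory.
#' @return A `session_trace` (detections reconstructed from the timeline).
#' @export
read_trace <- function(dir) {
  tl <- utils::read.table(file.path(dir, "trace_events.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  oc <- utils::read.table(file.path(dir, "outcomes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  oc$first_try_success <- as.logical(oc$first_try_success)
  script <- read_gait_script(file.path(dir, "gait_script.tsv"))
  truth <- read_events(file.path(dir, "truth_events.tsv"))
  det <- tl[tl$event == "bci_unlock", c("time"), drop = FALSE]
  structure(list(timeline = tl, detections = det, script = script,
                 outcomes = oc, truth_events = truth),
            class = "session_trace")
}

write_tsv_raw <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(names(df), collapse = "\t"),
               do.call(paste, c(unname(as.list(df)), sep = "\t"))),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
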