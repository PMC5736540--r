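#' Per-segment success report
#'
#' Counts walking (swing-phase) unlock attempts and first-try successes in
#' one segment. The denominator is the number of occasions the knee had to
#' be unlocked; the numerator the number unlocked on the first effort.
#' Sit-down attempts are reported separately by [session_summary()], not in
#' segment rates. With zero attempts the rate is `NA`, not 0.
#'
#' @param trace a `session_trace`.
#' @param segment_id segment identifier present in the gait script.
#' @return list of class `segment_report`: `segment_id`, `n_attempts`,
#'   `n_first_try`, `success_rate` (percent, full precision;
#'   print rounds to one decimal), `false_positives`, `mean_latency`.
#' @export
segment_success_rate <- function(trace, segment_id) {
  if (!segment_id %in% trace$script$segment_id) {
    stop("unknown segment ", segment_id, call. = FALSE)
  }
  oc <- trace$outcomes
  oc <- oc[oc$segment_id == segment_id & oc$kind == "swing_attempt", ,
           drop = FALSE]
  n <- nrow(oc)
  n_first <- sum(oc$first_try_success)
  lat <- oc$latency[oc$first_try_success]
  structure(
    list(segment_id = segment_id, n_attempts = n, n_first_try = n_first,
         success_rate = if (n > 0) 100 * n_first / n else NA_real_,
         false_positives = segment_false_positives(trace, segment_id),
         mean_latency = if (length(lat)) mean(lat) else NA_real_),
    class = "segment_report"
  )
}

#' @export
print.segment_report <- function(x, ...) {
  cat(sprintf("segment %s: %d/%d first-try (%s), %d false positive(s)\n",
              x$segment_id, x$n_first_try, x$n_attempts,
              if (is.na(x$success_rate)) "NA" else
                sprintf("%.1f%%", x$success_rate),
              x$false_positives))
  invisible(x)
}

# unlock transitions inside no-intent phases (stance, rest, stand_up) of one
# segment
segment_false_positives <- function(trace, segment_id) {
  ph <- trace$script[trace$script$segment_id == segment_id &
                       trace$script$kind %in% c("stance", "rest",
                                                "stand_up"), ,
                     drop = FALSE]
  count_unlocks_in(trace, ph)
}

count_unlocks_in <- function(trace, phases) {
  tl <- trace$timeline
  ul <- tl$time[tl$event == "bci_unlock" & !tl$redundant &
                  tl$state_after == "UNLOCKED"]
  sum(vapply(ul, function(t) {
    any(t >= phases$start & t < phases$start + phases$duration)
  }, TRUE))
}

#' False-positive count of a trace
#'
#' Unlock transitions occurring in phases with no pending intent (stance,
#' rest, stand_up). The clinical requirement is that the switch never
#' activates spontaneously: an unexpected unlock during stance would risk a
#' fall.
#'
#' @param trace a `session_trace`.
#' @return integer count.
#' @export
false_positive_count <- function(trace) {
  ph <- trace$script[trace$script$kind %in% c("stance", "rest", "stand_up"),
                     , drop = FALSE]
  count_unlocks_in(trace, ph)
}

#' Detection latency statistics
#'
#' Latency is detection time minus intent onset per matched attempt
#' (synthetic sessions only — requires ground-truth intents). Unmatched
#' attempts are excluded from the statistics and counted as misses.
#'
#' @param trace a `session_trace`.
#' @param truth an [event_list()] with `self_paced_intent` rows; defaults to
#'   the trace's own truth events.
#' @return list: `latencies` (s, per successful attempt), `median`, `p90`,
#'   `n_hits`, `n_misses`.
#' @export
detection_latency <- function(trace, truth = trace$truth_events) {
  if (is.null(truth) || !any(truth$label == "self_paced_intent")) {
    stop("latency needs ground-truth intent events (synthetic sessions)",
         call. = FALSE)
  }
  oc <- trace$outcomes
  lat <- oc$latency[oc$first_try_success]
  list(latencies = lat,
       median = if (length(lat)) stats::median(lat) else NA_real_,
       p90 = if (length(lat)) unname(stats::quantile(lat, 0.9)) else
         NA_real_,
       n_hits = sum(oc$first_try_success),
       n_misses = sum(!oc$first_try_success))
}

#' Whole-session summary
#'
#' Per-segment walking reports plus the overall success-rate range, total
#' false positives, and sit-attempt outcomes in a separate column (whether
#' sit-down unlocks belong in segment rates is ambiguous, so they are kept
#' apart).
#'
#' @param trace a `session_trace`.
#' @return list of class `session_summary`: `segments` (data frame),
#'   `rate_range`, `total_false_positives`, `sit_attempts`,
#'   `sit_successes`.
#' @export
session_summary <- function(trace) {
  seg_ids <- sort(unique(trace$outcomes$segment_id[
    trace$outcomes$kind == "swing_attempt"]))
  reports <- lapply(seg_ids, segment_success_rate, trace = trace)
  segments <- do.call(rbind, lapply(reports, function(r) {
    data.frame(segment_id = r$segment_id, n_attempts = r$n_attempts,
               n_first_try = r$n_first_try, success_rate = r$success_rate,
               false_positives = r$false_positives,
               mean_latency = r$mean_latency)
  }))
  rates <- segments$success_rate[!is.na(segments$success_rate)]
  sit <- trace$outcomes[trace$outcomes$kind == "sit_attempt", , drop = FALSE]
  structure(
    list(segments = segments,
         rate_range = if (length(rates)) range(rates) else
           c(NA_real_, NA_real_),
         total_false_positives = false_positive_count(trace),
         sit_attempts = nrow(sit),
         sit_successes = sum(sit$first_try_success)),
    class = "session_summary"
  )
}

#' @export
print.session_summary <- function(x, ...) {
  seg <- x$segments
  for (i in seq_len(nrow(seg))) {
    cat(sprintf("segment %s: %d/%d first-try (%s)\n", seg$segment_id[i],
                seg$n_first_try[i], seg$n_attempts[i],
                if (is.na(seg$success_rate[i])) "NA" else
                  sprintf("%.1f%%", seg$success_rate[i])))
  }
  cat(sprintf("success range %.1f-%.1f%%, %d false positive(s), sit %d/%d\n",
              x$rate_range[1], x$rate_range[2], x$total_false_positives,
              x$sit_successes, x$sit_attempts))
  invisible(x)
}

#' Write a session report
#'
#' One TSV row per segment (rates to one decimal) and a summary footer with
#' the overall range, total false positives and sit outcomes.
#'
#' @param summary a `session_summary`.
#' @param path output file.
#' @export
write_report <- function(summary, path) {
  seg <- summary$segments
  rows <- vapply(seq_len(nrow(seg)), function(i) {
    paste(seg$segment_id[i], seg$n_attempts[i], seg$n_first_try[i],
          if (is.na(seg$success_rate[i])) "NA" else
            sprintf("%.1f", seg$success_rate[i]),
          seg$false_positives[i],
          if (is.na(seg$mean_latency[i])) "NA" else
            sprintf("%.3f", seg$mean_latency[i]),
          sep = "\t")
  }, "")
  footer <- c(
    sprintf("# success_rate_range\t%.1f\t%.1f", summary$rate_range[1],
            summary$rate_range[2]),
    sprintf("# total_false_positives\t%d", summary$total_false_positives),
    sprintf("# sit_attempts_first_try\t%d/%d", summary$sit_successes,
            summary$sit_attempts)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste("segment_id", "n_attempts", "n_first_try",
                     "success_rate", "false_positives", "mean_latency",
                     sep = "\t"),
               rows, footer),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
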