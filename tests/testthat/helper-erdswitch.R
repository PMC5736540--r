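# Shared fixtures, built in code at test time.

# small cued training config (short trials keep tests fast)
quiet_cued_cfg <- function(n_trials = 10, depth = 0.6,
                           noise = list(pink_amplitude = 1,
                                        white_amplitude = 0.25)) {
  session_config("cued_training", noise = noise,
                 erd = list(depth = depth),
                 cued = list(n_trials = n_trials, trial_interval = 4,
                             first_cue = 3))
}

# small self-paced walk config; baseline shortened when no calibration runs
quiet_walk_cfg <- function(n_segments = 1, attempts = 3, depth = 0.6,
                           baseline = 62.5,
                           noise = list(pink_amplitude = 1,
                                        white_amplitude = 0.25)) {
  session_config("self_paced_walk", noise = noise,
                 erd = list(depth = depth, duration = 1.5),
                 walk = list(n_segments = n_segments,
                             attempts_per_segment = attempts,
                             baseline_duration = baseline))
}

# channel weights whose Laplacian residual is nonzero on every channel
# (coherent pure-tone fixtures would otherwise cancel exactly on C3)
oracle_weights <- function() {
  c(C5 = 1, C3 = 0.2, C1 = 0.8, CZ = 0.3, C2 = 0.9, C4 = 0.1)
}

# noiseless pure-tone self-paced session with per-attempt ERD depths,
# reusing the gait script of a template session with the same layout
pure_walk_session <- function(depths, baseline = 5, seed = 1) {
  n_att <- length(depths)
  tpl <- generate_session(quiet_walk_cfg(n_segments = 1, attempts = n_att,
                                         baseline = baseline), seed = seed)
  att <- tpl$gait_script[tpl$gait_script$kind %in%
                           c("swing_attempt", "sit_attempt"), ]
  stopifnot(nrow(att) == n_att + 1)  # + sit attempt
  depths <- c(depths, 1)
  events <- Map(function(t0, d) {
    erd_event(t0, 0.5, 1.5, depth = d, label = "self_paced_intent")
  }, att$start + 0.5, depths)
  bg <- generate_background(recording_duration(tpl$recording), 250,
                            noise = noise_spec(0, 0), seed = seed)
  rhythm <- rhythm_spec(20, 4, 3, oracle_weights(), pure_tone = TRUE)
  ses <- apply_erd_events(bg, rhythm, events, seed = seed)
  ses$gait_script <- tpl$gait_script
  ses$baseline_window <- c(0, baseline)
  ses
}

# single- or multi-channel pure sine recording
tone_recording <- function(freq = 20, duration = 10, fs = 250,
                           amplitude = 1, n_channels = 1) {
  t <- (seq_len(round(duration * fs)) - 1) / fs
  x <- amplitude * sin(2 * pi * freq * t)
  dat <- matrix(rep(x, each = n_channels), nrow = n_channels)
  eeg_recording(dat, fs, paste0("ch", seq_len(n_channels)))
}

# independent shrinkage-LDA oracle: covariances accumulated by explicit
# outer-product sums, weights via explicit inverse
brute_lda <- function(x, y, positive, shrinkage) {
  xp <- x[y == positive, , drop = FALSE]
  xn <- x[y != positive, , drop = FALSE]
  mp <- colMeans(xp)
  mn <- colMeans(xn)
  scatter <- function(m, mu) {
    s <- matrix(0, ncol(m), ncol(m))
    for (i in seq_len(nrow(m))) {
      d <- m[i, ] - mu
      s <- s + outer(d, d)
    }
    s
  }
  s <- (scatter(xp, mp) + scatter(xn, mn)) / (nrow(xp) + nrow(xn) - 2)
  p <- ncol(x)
  s <- (1 - shrinkage) * s + shrinkage * (sum(diag(s)) / p) * diag(p)
  w <- solve(s) %*% (mp - mn)
  list(weights = drop(w), bias = -sum(w * (mp + mn)) / 2)
}

# independent brute-force knee FSM for replay checks
brute_fsm <- function(events_df) {
  state <- "LOCKED"
  after <- character(nrow(events_df))
  for (i in seq_len(nrow(events_df))) {
    e <- events_df$event[i]
    if (state == "LOCKED" && e == "bci_unlock") state <- "UNLOCKED"
    else if (state == "UNLOCKED" && e == "knee_extension") state <- "LOCKED"
    after[i] <- state
  }
  after
}
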