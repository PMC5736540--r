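test_that("zero-noise background is an all-zero matrix of the right shape", {
  bg <- generate_background(10, 250, default_montage(),
                            noise_spec(0, 0), seed = 1)
  expect_equal(dim(bg$data), c(6L, 2500L))
  expect_true(all(bg$data == 0))
  expect_error(generate_background(-1, 250), "duration")
  expect_error(generate_background(10, 50), "fs")
})

test_that("background generation is deterministic under a fixed seed", {
  a <- generate_background(10, 250, seed = 7)
  b <- generate_background(10, 250, seed = 7)
  expect_identical(a$data, b$data)
  expect_lt(max(abs(rowMeans(a$data))), 0.5)
})

test_that("pink-only background has ~1/f spectral slope", {
  bg <- generate_background(100, 250, noise = noise_spec(3, 0), seed = 3)
  sp <- welch_psd(bg$data[1, ], 250, nperseg = 500)
  sel <- sp$freq >= 2 & sp$freq <= 40
  slope <- unname(coef(lm(log(sp$psd[sel]) ~ log(sp$freq[sel])))[2])
  expect_lt(slope, -0.7)
  expect_gt(slope, -1.3)
})

test_that("rhythm injection is additive, narrowband and weight-masked", {
  bg <- generate_background(20, 250, noise = noise_spec(0, 0), seed = 1)
  r0 <- rhythm_spec(20, 4, amplitude = 0)
  expect_identical(inject_rhythm(bg, r0, seed = 1)$data, bg$data)

  r <- rhythm_spec(20, 4, amplitude = 3)
  rec <- inject_rhythm(bg, r, seed = 2)
  inband <- mean(band_power(rec$data[1, ], 250, freq_band(16, 24))$power)
  outband <- mean(band_power(rec$data[1, ], 250, freq_band(30, 38))$power)
  expect_gt(inband / outband, 100)

  # >= 95% of PSD mass within center +/- bandwidth
  sp <- welch_psd(rec$data[1, ], 250, nperseg = 500)
  df <- sp$freq[2] - sp$freq[1]
  mass_in <- sum(sp$psd[sp$freq >= 16 & sp$freq <= 24]) * df
  expect_gt(mass_in / (sum(sp$psd) * df), 0.95)

  rc3 <- rhythm_spec(20, 4, 3, channel_weights = c(C3 = 1))
  rec3 <- inject_rhythm(bg, rc3, seed = 2)
  other <- setdiff(rownames(rec3$data), "C3")
  expect_true(all(rec3$data[other, ] == 0))
  expect_gt(sd(rec3$data["C3", ]), 0)

  expect_error(
    inject_rhythm(bg, rhythm_spec(20, 4, 3, channel_weights = c(XX = 1))),
    "valid labels.*C5"
  )
})

test_that("ERD events attenuate rhythm power by (1-depth)^2", {
  bg <- generate_background(10, 250, noise = noise_spec(0, 0), seed = 1)
  tone <- rhythm_spec(20, 4, 3, pure_tone = TRUE)

  # depth 0 reproduces plain injection under the same seed
  s0 <- apply_erd_events(bg, tone, list(erd_event(4, depth = 0)), seed = 5)
  expect_identical(s0$recording$data, inject_rhythm(bg, tone, seed = 5)$data)

  # depth 1, noiseless: in-band power inside the window is exactly zero
  s1 <- apply_erd_events(bg, tone, list(erd_event(4, 0.5, 1, depth = 1)))
  win <- s1$recording$data[4, 1126:1375]   # [4.5, 5.5) s
  expect_true(all(win == 0))

  # depth 0.4: power ratio (0.6)^2 = 0.36, ERD% = -64 exactly (pure tone)
  s <- apply_erd_events(bg, tone, list(erd_event(4, 0.5, 1, depth = 0.4)))
  b <- freq_band(16, 24)
  p_evt <- mean(band_power(s$recording$data[4, 1126:1375], 250, b)$power)
  p_base <- mean(band_power(s$recording$data[4, 1:1000], 250, b)$power)
  expect_equal(p_evt / p_base, 0.36, tolerance = 1e-5)
  expect_equal(erd_percent(p_evt, p_base), -64, tolerance = 1e-5)
})

test_that("overlapping or out-of-range ERD windows are rejected", {
  bg <- generate_background(10, 250, noise = noise_spec(0, 0), seed = 1)
  tone <- rhythm_spec(20, 4, 3, pure_tone = TRUE)
  expect_error(
    apply_erd_events(bg, tone, list(erd_event(2, 0.5, 2), erd_event(3, 0.5, 2))),
    "collides"
  )
  expect_error(
    apply_erd_events(bg, tone, list(erd_event(9.5, 0.5, 2))),
    "past recording end"
  )
})

test_that("ground-truth fidelity: band-power ratio converges to (1-depth)^2", {
  bg <- generate_background(30, 250, noise = noise_spec(0, 0), seed = 2)
  b <- freq_band(16, 24)
  for (depth in c(0.2, 0.4, 0.6)) {
    tone <- rhythm_spec(20, 4, 3, pure_tone = TRUE)
    s <- apply_erd_events(bg, tone,
                          list(erd_event(10, 0.5, 4, depth = depth)))
    x <- s$recording$data[4, ]
    p_evt <- mean(band_power(x[(10.5 * 250 + 1):(14.5 * 250)], 250, b)$power)
    p_base <- mean(band_power(x[1:2000], 250, b)$power)
    expect_equal(p_evt / p_base, (1 - depth)^2, tolerance = 1e-5)
  }
})

test_that("cued_training preset alternates move/rest with correct counts", {
  ses <- generate_session(quiet_cued_cfg(n_trials = 20), seed = 4)
  tab <- table(ses$truth_events$label)
  expect_equal(unname(tab["cued_move"]), 10L)
  expect_equal(unname(tab["cued_rest"]), 10L)
  # ERD windows only for move trials, all inside the recording
  expect_equal(unname(tab["erd_window"]), 10L)
  ends <- ses$truth_events$onset + ses$truth_events$duration
  expect_true(all(ends <= recording_duration(ses$recording)))
})

test_that("self_paced_walk preset couples intents to script attempts", {
  ses <- generate_session(quiet_walk_cfg(n_segments = 2, attempts = 4,
                                         baseline = 10), seed = 4)
  n_intents <- sum(ses$truth_events$label == "self_paced_intent")
  expect_equal(n_intents, 9L)  # 2 x 4 swing + 1 sit
  att <- ses$gait_script[ses$gait_script$kind %in%
                           c("swing_attempt", "sit_attempt"), ]
  expect_equal(nrow(att), 9L)
  ints <- ses$truth_events$onset[ses$truth_events$label ==
                                   "self_paced_intent"]
  expect_true(all(ints >= att$start & ints < att$start + att$duration))
})

test_that("identical (config, seed) reproduces a session byte-identically", {
  cfg <- quiet_cued_cfg(n_trials = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_session(generate_session(cfg, 11), d1)
  write_session(generate_session(cfg, 11), d2)
  for (f in c("recording.edf", "events.tsv", "config.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
})

test_that("session config rejects unknown fields", {
  expect_error(session_config("cued_training", cued = list(n_trial = 5)),
               "unknown config field 'cued.n_trial'")
  expect_error(session_config("cued_training", noise = list(pink = 1)),
               "unknown config field 'noise.pink'")
})
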