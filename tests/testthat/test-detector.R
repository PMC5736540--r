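fake_stream <- function(times, erd) {
  structure(list(times = times, features = matrix(erd, ncol = 1),
                 pooled_erd = erd, band = freq_band(16, 24),
                 mode = "raw_erd"),
            class = "feature_series")
}

test_that("features are causal, stop at the last full window, and track ERD", {
  bg <- generate_background(30, 250, noise = noise_spec(0.3, 0.05), seed = 1)
  rhythm <- rhythm_spec(20, 4, 3)
  ses <- apply_erd_events(bg, rhythm,
                          list(erd_event(10, 0.5, 4, depth = 0.4)), seed = 2)
  proc <- laplacian(bandpass(ses$recording,
                             filter_spec(1, 100, mode = "causal_online")))
  bs <- baseline_stats(proc, freq_band(16, 24), c(2, 9))
  feats <- extract_features(proc, freq_band(16, 24), baseline = bs,
                            mode = "raw_erd")
  expect_lte(max(feats$times), 30)
  expect_gt(max(feats$times), 29.5)

  # no-ERD stretch: pooled ERD near zero
  pre <- feats$pooled_erd[feats$times > 2 & feats$times < 9]
  expect_lt(abs(mean(pre)), 20)
  # inside the event window (fully-contained windows): strongly negative
  evt <- feats$pooled_erd[feats$times - 0.5 >= 11 & feats$times <= 14]
  expect_lte(mean(evt), -40)

  expect_error(extract_features(proc, freq_band(16, 24), mode = "raw_erd"),
               "configuration error")
})

test_that("detector honors threshold, dwell and refractory", {
  times <- seq(0.5, 60, by = 0.125)
  cfg <- detector_config(threshold = -50, dwell = 0.5, refractory = 3,
                         mode = "raw_erd")

  # flat rest: no detections
  expect_equal(nrow(detect_online(fake_stream(times, rep(0, length(times))),
                                  config = cfg)), 0L)

  # one sustained ERD of 1.5 s starting at 10 s
  erd <- rep(0, length(times))
  erd[times >= 10 & times < 11.5] <- -80
  det <- detect_online(fake_stream(times, erd), config = cfg)
  expect_equal(nrow(det), 1L)
  expect_gte(det$time, 10 + 0.5 - 0.2)
  expect_lte(det$time, 11.5 + 0.5)

  # two events 1 s apart with refractory 5: only one fires
  erd2 <- rep(0, length(times))
  erd2[times >= 10 & times < 11] <- -80
  erd2[times >= 12 & times < 13] <- -80
  cfg5 <- detector_config(threshold = -50, dwell = 0.5, refractory = 5,
                          mode = "raw_erd")
  expect_equal(nrow(detect_online(fake_stream(times, erd2), config = cfg5)),
               1L)

  # k well-separated events with refractory < spacing: exactly k
  erd3 <- rep(0, length(times))
  for (t0 in c(10, 25, 40)) erd3[times >= t0 & times < t0 + 1.5] <- -80
  expect_equal(nrow(detect_online(fake_stream(times, erd3), config = cfg)),
               3L)

  bad <- fake_stream(c(1, 0.5, 2), c(0, 0, 0))
  expect_error(detect_online(bad, config = cfg), "increasing")
})

test_that("detections are invariant to future samples (causality)", {
  times <- seq(0.5, 120, by = 0.125)
  set.seed(7)
  erd <- rnorm(length(times), 0, 10)
  erd[times >= 30 & times < 31.5] <- -80
  cfg <- detector_config(threshold = -50, dwell = 0.5, refractory = 3,
                         mode = "raw_erd")
  det_full <- detect_online(fake_stream(times, erd), config = cfg)
  cut <- times <= 40
  det_cut <- detect_online(fake_stream(times[cut], erd[cut]), config = cfg)
  keep <- det_full$time <= 40
  expect_equal(det_full$time[keep], det_cut$time)
})

test_that("threshold calibration is self-consistent and monotone", {
  set.seed(8)
  times <- seq(0.5, 600, by = 0.125)
  scores <- rnorm(length(times), -2, 1)
  cfg <- detector_config(dwell = 0.5, refractory = 3, mode = "lda_score")

  thr0 <- calibrate_threshold(list(times = times, values = scores), 0, cfg)
  cfg0 <- cfg
  cfg0$threshold <- thr0
  st <- structure(list(times = times,
                       features = matrix(scores, ncol = 1),
                       pooled_erd = NULL),
                  class = "feature_series")
  m1 <- structure(list(weights = 1, bias = 0), class = "lda_model")
  expect_equal(nrow(detect_online(st, m1, cfg0)), 0L)

  thr2 <- calibrate_threshold(list(times = times, values = scores), 2, cfg)
  expect_lte(thr2, thr0)

  # degenerate: all-equal rest scores -> threshold strictly past them
  thr_c <- calibrate_threshold(list(times = times,
                                    values = rep(1.5, length(times))),
                               0, cfg)
  expect_gt(thr_c, 1.5)

  # raw mode mirrors: calibrated threshold is detection-free on the rest data
  cfg_raw <- detector_config(dwell = 0.5, refractory = 3, mode = "raw_erd")
  thr_r <- calibrate_threshold(list(times = times, values = scores), 0,
                               cfg_raw)
  cfg_raw$threshold <- thr_r
  expect_equal(nrow(detect_online(fake_stream(times, scores),
                                  config = cfg_raw)), 0L)
  expect_lt(thr_r, mean(scores))

  expect_error(
    calibrate_threshold(list(times = seq(0.5, 30, 0.125),
                             values = rnorm(237)), 0, cfg),
    "60 s")
})
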