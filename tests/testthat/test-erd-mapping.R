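test_that("band power recovers analytic sine power", {
  x <- sin(2 * pi * 20 * (0:2499) / 250)  # unit amplitude -> power 0.5
  bp <- band_power(x, 250, freq_band(16, 24))
  expect_equal(mean(bp$power), 0.5, tolerance = 0.05)
  expect_equal(length(bp$power), floor((2500 - 125) / 31) + 1)

  expect_true(all(band_power(rep(0, 2500), 250, freq_band(16, 24))$power == 0))

  out <- band_power(x, 250, freq_band(30, 40))
  expect_lt(mean(out$power) / mean(bp$power), 0.01)

  expect_error(band_power(x, 250, freq_band(100, 130)), "Nyquist")
  expect_error(band_power(x, 250, freq_band(16, 24), window_len = 0.02),
               ">= 8 samples")
})

test_that("erd_percent follows the classical convention", {
  expect_equal(erd_percent(1, 1), 0)
  expect_equal(erd_percent(0.36, 1), -64)
  expect_equal(erd_percent(2, 1), 100)
  expect_equal(erd_percent(0, 5), -100)
  expect_error(erd_percent(1, 0), "R must be > 0")
  expect_error(erd_percent(-1, 1), "P must be >= 0")
})

test_that("ERD% is invariant to signal scaling", {
  ses <- generate_session(quiet_cued_cfg(n_trials = 6), seed = 5)
  b <- freq_band(16, 24)
  x <- ses$recording$data["CZ", ]
  p1 <- band_power(x, 250, b)$power
  p2 <- band_power(3.5 * x, 250, b)$power
  r1 <- mean(p1[1:10]); r2 <- mean(p2[1:10])
  expect_equal(erd_percent(p1, r1), erd_percent(p2, r2), tolerance = 1e-9)
})

test_that("time-frequency map localizes the injected ERD", {
  cfg <- quiet_cued_cfg(n_trials = 12, depth = 0.4,
                        noise = list(pink_amplitude = 0.3,
                                     white_amplitude = 0.05))
  ses <- generate_session(cfg, seed = 8)
  proc <- laplacian(bandpass(ses$recording, filter_spec(1, 100)))
  ep <- epoch(proc, ses$truth_events, -1.5, 2.5,
              labels_filter = "cued_move")
  map <- erd_time_frequency(ep, c(-1, 0), seq(6, 34, by = 2))
  idx <- which(map$values == min(map$values), arr.ind = TRUE)[1, ]
  f_min <- map$freqs[idx[1]]
  t_min <- map$times[idx[2]]
  expect_gte(f_min, 16)
  expect_lte(f_min, 24)
  expect_gte(t_min, 0.5 - 0.3)   # window-granularity slack
  in_band <- map$freqs >= 16 & map$freqs <= 24
  post <- map$times >= 0.75 & map$times <= 1.25
  expect_equal(mean(map$values[in_band, post]), -64, tolerance = 15)
  expect_gte(min(map$values), -100)
})

test_that("null sessions give a flat map and single trials are flagged", {
  cfg <- quiet_cued_cfg(n_trials = 40, depth = 0)
  ses <- generate_session(cfg, seed = 9)
  proc <- laplacian(bandpass(ses$recording, filter_spec(1, 100)))
  ep <- epoch(proc, ses$truth_events, -1.5, 2.5,
              labels_filter = "cued_move")
  map <- erd_time_frequency(ep, c(-1, 0), seq(6, 34, by = 2))
  # null width measured over replicate seeds: q95 of |ERD| ~ 40-58 and
  # in-band post-cue means within +/-30 at 20 trial averages (the slow
  # rhythm amplitude modulation dominates); no cell approaches -100
  expect_lt(unname(quantile(abs(map$values), 0.95)), 70)
  inb <- map$freqs >= 16 & map$freqs <= 24
  post <- map$times >= 0.75 & map$times <= 1.25
  expect_lt(abs(mean(map$values[inb, post])), 40)

  ep1 <- ep
  ep1$data <- ep$data[1, , , drop = FALSE]
  ep1$labels <- ep$labels[1]
  map1 <- erd_time_frequency(ep1, c(-1, 0), seq(6, 34, by = 2))
  expect_true(isTRUE(attr(map1, "low_reliability")))

  expect_error(erd_time_frequency(ep, c(0, 0.5)), "before the cue")
})

test_that("select_band recovers the injected band and breaks ties low", {
  cfg <- quiet_cued_cfg(n_trials = 12, depth = 0.6)
  ses <- generate_session(cfg, seed = 10)
  proc <- laplacian(bandpass(ses$recording, filter_spec(1, 100)))
  ep <- epoch(proc, ses$truth_events, -1.5, 2.5,
              labels_filter = "cued_move")
  map <- erd_time_frequency(ep, c(-1, 0), seq(6, 34, by = 2))
  band <- select_band(map, freq_band(8, 30), min_width = 8)
  overlap <- max(0, min(band$high, 24) - max(band$low, 16))
  expect_gte(overlap / 8, 0.75)
  expect_true(band$low <= 20 && band$high >= 20)

  # uniform zero map: lowest allowed band, flagged
  flat <- map
  flat$values[] <- 0
  b0 <- select_band(flat, freq_band(8, 30), 8)
  expect_equal(b0$low, 8)
  expect_equal(b0$high, 16)
  expect_true(isTRUE(attr(b0, "no_reactive_band")))

  # two equal troughs far enough apart that candidate bands tie exactly:
  # the lower band wins
  two <- map
  two$values[] <- 0
  two$values[two$freqs == 10, two$times >= 0] <- -50
  two$values[two$freqs == 28, two$times >= 0] <- -50
  bt <- select_band(two, freq_band(8, 30), 8)
  expect_lte(bt$low, 10)
  expect_gte(bt$high, 10)
  expect_lt(bt$high, 28)

  expect_error(select_band(map, freq_band(10, 14), 8), "narrower")
})

test_that("tf map serialization round trips", {
  m <- structure(list(values = matrix(c(-10, 5, 0, 2.5), 2),
                      freqs = c(10, 20), times = c(0, 0.5),
                      channel = "pooled"), class = "tf_map")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tf_map(m, path)
  back <- read_tf_map(path)
  expect_equal(back$freqs, m$freqs)
  expect_equal(back$times, m$times, tolerance = 1e-4)
  expect_equal(unname(back$values), unname(m$values), tolerance = 1e-6)
})

test_that("baseline stats require a rest window inside the recording", {
  ses <- generate_session(quiet_walk_cfg(baseline = 5), seed = 1)
  proc <- laplacian(bandpass(ses$recording, filter_spec(1, 100)))
  bs <- baseline_stats(proc, freq_band(16, 24), c(0, 5))
  expect_length(bs$R, 6)
  expect_true(all(bs$R > 0))
  expect_error(baseline_stats(proc, freq_band(16, 24), c(0, 1e4)),
               "inside the recording")
})
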