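test_that("re-referencing subtracts the reference series", {
  rec <- tone_recording(n_channels = 3, duration = 2)
  # zero reference: unchanged
  expect_equal(rereference(rec, rep(0, 500))$data, rec$data)
  # common mode: all channels equal to the reference -> zero out
  out <- rereference(rec, rec$data[1, ])
  expect_true(all(abs(out$data) < 1e-12))
  # plain arithmetic on a single sample
  one <- eeg_recording(matrix(5), 250, "C3")
  expect_equal(unname(rereference(one, 2)$data[1, 1]), 3)
  expect_error(rereference(rec, rep(0, 10)), "500")
})

test_that("rereference is linear in its input", {
  rec <- tone_recording(n_channels = 2, duration = 1)
  ref <- rnorm(250)
  a <- rereference(rec, ref)$data
  rec2 <- eeg_recording(2 * rec$data, rec$fs, rec$channel_names)
  b <- rereference(rec2, 2 * ref)$data
  expect_equal(b, 2 * a, tolerance = 1e-12)
})

test_that("bandpass passes in-band tones and attenuates out-of-band", {
  fs <- 250
  edge <- fs  # discard 1 s per side
  spec <- filter_spec(16, 24, order = 4, mode = "zero_phase_offline")
  rms <- function(x) sqrt(mean(x^2))

  tone20 <- tone_recording(20, 10, fs)
  out20 <- bandpass(tone20, spec)$data[1, (edge + 1):(2250)]
  gain <- rms(out20) / rms(tone20$data[1, (edge + 1):(2250)])
  expect_gt(gain, 0.95)
  expect_lt(gain, 1.05)

  tone50 <- tone_recording(50, 10, fs)
  out50 <- bandpass(tone50, spec)$data[1, (edge + 1):(2250)]
  atten_db <- -20 * log10(rms(out50) / rms(tone50$data[1, (edge + 1):(2250)]))
  expect_gte(atten_db, 20)

  dc <- eeg_recording(matrix(1, 1, 2500), fs, "ch1")
  out_dc <- bandpass(dc, filter_spec(1, 100))$data[1, (edge + 1):(2250)]
  expect_lt(max(abs(mean(out_dc))), 1e-6)

  expect_error(bandpass(tone20, filter_spec(1, 125)), "Nyquist|fs/2")
})

test_that("zero-phase filtering is time-symmetric", {
  set.seed(1)
  x <- eeg_recording(matrix(rnorm(2000), 1), 250, "ch1")
  spec <- filter_spec(1, 40, mode = "zero_phase_offline")
  fwd <- bandpass(x, spec)$data[1, ]
  xr <- eeg_recording(matrix(rev(x$data[1, ]), 1), 250, "ch1")
  rev_filt <- rev(bandpass(xr, spec)$data[1, ])
  expect_equal(fwd[200:1800], rev_filt[200:1800], tolerance = 1e-3)
})

test_that("causal filtering never looks ahead", {
  set.seed(2)
  x <- rnorm(2000)
  spec <- filter_spec(1, 40, mode = "causal_online")
  full <- bandpass(eeg_recording(matrix(x, 1), 250, "a"), spec)$data[1, ]
  x2 <- x
  x2[1001:2000] <- rnorm(1000) * 10
  alt <- bandpass(eeg_recording(matrix(x2, 1), 250, "a"), spec)$data[1, ]
  expect_identical(full[1:1000], alt[1:1000])
})

test_that("laplacian matches its brute-force definition", {
  m <- default_montage()
  # flat field: all channels identical -> zero
  flat <- eeg_recording(matrix(1, 6, 100) * 3.7, 250, m$channel_names)
  expect_true(all(abs(laplacian(flat, m)$data) < 1e-12))

  # single-sample arithmetic: C3 = 5, neighbors C5 = C1 = 1 -> 4
  v <- matrix(c(1, 5, 1, 0, 0, 0), 6, 1)
  one <- eeg_recording(v, 250, m$channel_names)
  expect_equal(unname(laplacian(one, m)$data["C3", 1]), 4)

  set.seed(3)
  rec <- eeg_recording(matrix(rnorm(6000), 6), 250, m$channel_names)
  lap <- laplacian(rec, m)$data
  for (i in seq_len(6)) {
    nb <- match(m$neighbor_map[[m$channel_names[i]]], m$channel_names)
    for (t in c(1, 500, 1000)) {
      expect_equal(lap[i, t], rec$data[i, t] - mean(rec$data[nb, t]),
                   tolerance = 1e-12)
    }
  }

  bad <- montage_spec(c("A", "B"), "R", list(A = "B"))
  expect_error(laplacian(eeg_recording(matrix(0, 2, 10), 250, c("A", "Z")),
                         bad), "B")
})

test_that("channels without neighbors pass through flagged", {
  m <- montage_spec(c("A", "B"), "R", list(A = "B"))
  rec <- eeg_recording(rbind(1:10, rep(2, 10)), 250, c("A", "B"))
  out <- laplacian(rec, m)
  expect_equal(unname(out$data[2, ]), rep(2, 10))
  expect_identical(attr(out, "passthrough"), "B")
})

test_that("epoching bookkeeping, boundary drops and empty selections", {
  fs <- 250
  rec <- generate_background(45, fs, noise = noise_spec(1, 0), seed = 1)
  ev <- event_list(onset = seq(2, 38, by = 4), duration = rep(1, 10),
                   label = rep("cued_move", 10))
  ep <- epoch(rec, ev, tmin = -1, tmax = 2)
  expect_equal(dim(ep$data), c(10L, 6L, 750L))
  expect_equal(epoch_times(ep)[1], -1)

  ev2 <- event_list(0.5, 1, "cued_move")
  expect_warning(ep2 <- epoch(rec, ev2, -1, 2), "dropped")
  expect_equal(attr(ep2, "n_dropped"), 1L)
  expect_equal(dim(ep2$data)[1], 0L)

  ep3 <- epoch(rec, ev, -1, 2, labels_filter = "nothing")
  expect_equal(dim(ep3$data)[1], 0L)
  expect_error(epoch(rec, ev, 2, -1), "tmin")
})
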