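test_that("EDF write/read round-trips within 16-bit quantisation", {
  ep <- toy_epoch(4)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(ep, f)
  rec <- read_edf(f)
  expect_equal(rec$fs, 128)
  expect_identical(rec$channel_names, EEG_CHANNELS)
  q <- max(apply(ep$data, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(rec$data - ep$data)), 2 * q)

  expect_error(read_edf(f, channels = c("Fp1", "C4", "Oz")), "Oz")
  rec8 <- read_edf(f, channels = c("C4", "Fp1"))
  expect_identical(rownames(rec8$data), c("C4", "Fp1"))
  # a file lacking C4 names the absentee
  ep7 <- new_epoch(ep$data[1:7, ], fs = 128, channel_names = EEG_CHANNELS[1:7])
  f7 <- withr::local_tempfile(fileext = ".edf")
  write_edf(ep7, f7)
  expect_error(read_edf(f7, channels = EEG_CHANNELS), "C4")
  expect_error(read_edf(withr::local_tempfile()), "not found")
})

test_that("a five-minute 128 Hz recording has 38400 samples per channel", {
  spec <- signal_spec(band_amplitudes = c(alpha = 1), duration_s = 300,
                      n_channels = 2)
  ep <- generate_epoch(spec, 1)
  expect_equal(ncol(ep$data), 38400L)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(ep, f)
  expect_equal(ncol(read_edf(f)$data), 38400L)
})

test_that("DEAP-style archives round-trip with ratings and geometry intact", {
  tr <- generate_rated_trials(40, valence_dist = c(1, 4), arousal_dist = c(2, 7),
                              seed = 6)
  f <- withr::local_tempfile()
  write_deap_archive(tr, f)
  tr2 <- read_deap_archive(f)
  expect_length(tr2, 40L)
  expect_equal(dim(tr2[[1]]$signal), c(8L, 8064L))
  expect_equal(ncol(tr2[[1]]$signal) / tr2[[1]]$fs, 63) # 3 s baseline + 60 s
  expect_equal(vapply(tr2, `[[`, 0, "valence"), vapply(tr, `[[`, 0, "valence"))
  expect_equal(tr2[[7]]$signal, tr[[7]]$signal)

  bad <- tr[1:2]
  bad[[1]]$valence <- 0.5
  fb <- withr::local_tempfile()
  write_deap_archive(bad, fb)
  expect_error(read_deap_archive(fb), "\\[1, 9\\]")
  # truncated file -> format error citing the expected layout
  sz <- file.size(f)
  raw <- readBin(f, "raw", sz - 50000)
  ft <- withr::local_tempfile()
  writeBin(raw, ft)
  expect_error(read_deap_archive(ft), "8064")
})

test_that("band-pass keeps in-band tones and kills out-of-band ones", {
  fs <- 128
  t <- (0:2047) / fs
  s10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass(s10, fs)
  core <- 200:1800 # avoid filter edge transients
  expect_lt(abs(max(abs(y10[core])) - 1), 0.05)
  s1 <- sin(2 * pi * 1 * t)
  y1 <- bandpass(s1, fs)
  expect_lt(mean(y1[core]^2) / mean(s1^2), 0.01)
  expect_equal(bandpass(rep(0, 512), fs), rep(0, 512))
  expect_equal(length(y10), length(s10))
  expect_error(bandpass(s10, fs = 80), "exceed")
})

test_that("resampling preserves sub-Nyquist content and refuses upsampling", {
  expect_identical(resample_to(1:10, 128, 128), 1:10)
  fs_in <- 512
  x <- sin(2 * pi * 10 * (0:38399) / fs_in)
  y <- resample_to(x, fs_in, 128)
  expect_length(y, 9600L)
  ps <- welch_psd(y, fs = 128)
  expect_equal(ps$freq[which.max(ps$psd)], 10)
  expect_error(resample_to(x, 64, 128), "upsampling")
})

test_that("trial screening uses strict thresholds", {
  mk <- function(v, a) structure(list(valence = v, arousal = a),
                                 class = "rated_trial")
  expect_true(screen_trial(mk(2.0, 4.0)))
  expect_false(screen_trial(mk(2.5, 4.0))) # at the valence threshold
  expect_false(screen_trial(mk(1.0, 5.0))) # at the arousal threshold
  expect_error(screen_trial(mk(0.2, 4)), "\\[1, 9\\]")
  # monotone: lowering valence_max never adds trials
  tr <- generate_rated_trials(200, seed = 8)
  kept <- function(vm) sum(vapply(tr, screen_trial, logical(1), valence_max = vm))
  expect_true(all(diff(vapply(c(1.5, 2.5, 4, 6), kept, numeric(1))) >= 0))
})

test_that("steady-state cropping handles baselines and bounds", {
  tr <- generate_rated_trials(1, valence_dist = 2, arousal_dist = 2, seed = 5)[[1]]
  sig <- crop_steady_state(tr)
  expect_equal(ncol(sig), 5760L) # 45 s at 128 Hz
  # baseline offset: window starts at (3 + 15) s into the 8064-sample trial
  expect_equal(sig[1, 1], tr$signal[1, 18 * 128 + 1])
  no_base <- list(signal = tr$signal[, 1:7680, drop = FALSE], fs = 128)
  expect_equal(ncol(crop_steady_state(no_base)), 5760L)
  expect_error(crop_steady_state(tr, start = 20, end = 20), "empty-window")
  short <- list(signal = tr$signal[, 1:1000, drop = FALSE], fs = 128,
                baseline_s = 3)
  expect_error(crop_steady_state(short), "too short")
})

test_that("segmentation yields non-overlapping 960-sample epochs", {
  m <- matrix(rnorm(8 * 5760), nrow = 8, dimnames = list(EEG_CHANNELS, NULL))
  eps <- segment_epochs(m)
  expect_length(eps, 6L)
  expect_true(all(vapply(eps, is_standard_epoch, logical(1))))
  expect_equal(eps[[2]]$data[, 1], m[, 961])
  expect_length(segment_epochs(m[, 1:960, drop = FALSE]), 1L)
  expect_length(segment_epochs(m[, 1:959, drop = FALSE]), 0L)
})

test_that("channel selection reorders any montage to canonical order", {
  ep <- toy_epoch(9)
  big <- rbind(ep$data, O1 = rnorm(960), O2 = rnorm(960))
  shuffled <- big[rev(rownames(big)), ]
  out <- select_channels(shuffled)
  expect_identical(rownames(out), EEG_CHANNELS)
  expect_equal(out, ep$data)
  expect_identical(select_channels(ep)$data, ep$data)
  expect_error(select_channels(big[1:5, ]), "F8")
})

test_that("cohort balancing down-samples the majority class reproducibly", {
  co <- generate_cohort(4, seed = 2)           # 4 + 4
  extra <- generate_cohort(3, seed = 9)[1:3]   # 3 more depression
  unbal <- structure(c(co, extra), class = "eeg_cohort")
  bal <- balance_cohort(unbal, seed = 5)
  labs <- vapply(bal, function(s) s$label, integer(1))
  expect_equal(as.integer(table(labs)), c(4L, 4L))
  expect_identical(lapply(balance_cohort(unbal, seed = 5), `[[`, "seed"),
                   lapply(bal, `[[`, "seed"))
  expect_identical(balance_cohort(co, seed = 1)[], co[])
  onecls <- structure(co[5:8], class = "eeg_cohort")
  expect_error(balance_cohort(onecls), "both classes")
})

test_that("the trial pipeline composes into standardized labelled epochs", {
  tr <- generate_rated_trials(6, valence_dist = c(1, 4), arousal_dist = c(2, 7),
                              seed = 12)
  co <- trials_to_cohort(tr)
  n_kept <- attr(co, "n_trials_kept")
  expect_equal(length(co), 6L * n_kept) # 45 s / 7.5 s epochs per kept trial
  expect_true(all(vapply(co, function(s) is_standard_epoch(s$epoch), logical(1))))
  expect_true(all(vapply(co, function(s) s$label, integer(1)) == 0L))
})

test_that("filtering and resampling commute with channel selection", {
  ep <- toy_epoch(13)
  a <- bandpass(select_channels(ep$data), 128)
  b <- select_channels(bandpass(ep$data, 128))
  expect_equal(a, b, tolerance = 1e-10)
  spec <- signal_spec(band_amplitudes = c(alpha = 1), duration_s = 15,
                      n_channels = 8)
  big <- generate_epoch(spec, 3)
  a2 <- resample_to(select_channels(big$data, c("F3", "C4")), 128 * 2)
  # (treat the 128 Hz signal as if sampled at 256 to exercise the path)
  b2 <- resample_to(big$data, 128 * 2)[c("F3", "C4"), ]
  expect_equal(a2, b2, tolerance = 1e-10)
})

test_that("EDF cohort export round-trips through the manifest", {
  co <- generate_cohort(2, seed = 21)
  d <- withr::local_tempdir()
  write_cohort_edf(co, d)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  co2 <- read_cohort_edf(d)
  expect_length(co2, 4L)
  expect_equal(vapply(co2, function(s) s$label, integer(1)),
               vapply(co, function(s) s$label, integer(1)))
  err <- max(abs(co2[[1]]$epoch$data - co[[1]]$epoch$data))
  expect_lt(err, diff(range(co[[1]]$epoch$data)) / 65535 * 2)
})
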