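test_that("moving-average smoothing obeys its contracts", {
  V <- 1000 + sin(seq(0, 20, length.out = 200))
  s <- series_from_V(V)
  expect_equal(smooth_volume(s, 1), s)
  const <- series_from_V(rep(500, 50))
  expect_equal(smooth_volume(const, 7)$V, const$V)
  expect_error(smooth_volume(s, 4), class = "zh_parameter_error")
  expect_error(smooth_volume(s, 201), class = "zh_parameter_error")

  # white noise variance drops by the window factor
  set.seed(7)
  noise <- rnorm(1800)
  sn <- series_from_V(1e4 + noise)
  sm <- smooth_volume(sn, 5)
  expect_equal(var(sm$V[3:1798]), 1 / 5, tolerance = 0.2)
})

test_that("a noiseless 2 Hz sinusoid yields 120 beats at exactly 120 bpm", {
  t <- (0:1799) / 30
  s <- series_from_V(3e5 + 1e5 * sin(2 * pi * 2 * t))
  bt <- detect_beats(s)
  peaks <- attr(bt, "diastole_frames")
  expect_length(peaks, 120)
  ibis <- beat_intervals(bt)
  expect_equal(ibis, rep(0.5, 119))
  expect_equal(heart_rate(ibis)$bpm, 120, tolerance = 0.5 / 120)

  # independent peak-count oracle: brute-force local-maxima scan
  v <- 3e5 + 1e5 * sin(2 * pi * 2 * t)
  brute <- sum(v[2:1799] > v[1:1798] & v[2:1799] >= v[3:1800])
  expect_identical(length(peaks), as.integer(brute))
})

test_that("peak detection agrees with pracma on the smoothed sinusoid", {
  skip_if_not_installed("pracma")
  t <- (0:899) / 30
  s <- series_from_V(3e5 + 1e5 * sin(2 * pi * 2 * t))
  sm <- smooth_volume(s, 5)
  ours <- attr(detect_beats(s), "diastole_frames")
  ref <- pracma::findpeaks(sm$V, minpeakdistance = 5)
  expect_identical(length(ours), nrow(ref))
  expect_equal(sort(ours + 1L), sort(as.integer(ref[, 2])))
})

test_that("constant and too-short traces raise insufficient-beats errors", {
  expect_error(detect_beats(series_from_V(rep(1000, 300))),
               class = "zh_insufficient_beats")
  tbl <- fake_beat_table(10, 4, 10, 8, c(0L, 15L))
  attr(tbl, "diastole_frames") <- 0L
  expect_error(beat_intervals(tbl), class = "zh_insufficient_beats")
})

test_that("zero-noise simulator beats are recovered exactly", {
  sim <- simulate_track(preset_spec("control", seed = 31, jitter_px = 0,
                                    dropout_rate = 0))
  fit <- detect_beats(axis_lengths(sim$track))
  truth_frames <- sim$truth$beat_frames
  peaks <- attr(fit, "diastole_frames")
  expect_identical(length(peaks), length(truth_frames))
  expect_lte(max(abs(peaks - truth_frames)), 1)
  # reported measurement frames agree with the truth as well
  expect_lte(max(abs(fit$diastole_frame - truth_frames[-length(truth_frames)])), 1)
})

test_that("beat intervals are frame differences over fps", {
  expect_equal(beat_intervals(fake_beat_table(10, 4, 10, 8, c(0L, 15L, 30L))),
               c(0.5, 0.5))
  expect_equal(beat_intervals(fake_beat_table(10, 4, 10, 8, c(0L, 30L))), 1)
})

test_that("interval jitter magnitude survives the pipeline", {
  sim <- simulate_track(preset_spec("control", seed = 32, rr_sd_s = 0.02,
                                    rr_ar1 = 0, duration_s = 45))
  expect_gte(length(sim$truth$ibis), 100)
  fit <- heart_scan(sim$track)
  expect_equal(sd(beat_intervals(fit$beats)), 0.02, tolerance = 0.25)
})

test_that("heart rate reports both estimators", {
  expect_equal(heart_rate(rep(0.5, 10))$bpm, 120)
  expect_equal(heart_rate(1)$bpm, 60)
  hr <- heart_rate(c(0.4, 0.6))
  expect_equal(hr$bpm, 125)                # mean(150, 100)
  expect_equal(hr$bpm_count_based, 120)    # 2 beats over 1.0 s
  expect_error(heart_rate(numeric(0)), class = "zh_insufficient_beats")
  expect_error(heart_rate(c(0.5, -0.1)), class = "zh_domain_error")
})

test_that("detection is invariant to affine volume rescaling", {
  sim <- simulate_track(preset_spec("control", seed = 33, duration_s = 20))
  s <- axis_lengths(filter_by_likelihood(sim$track, 0.6))
  s2 <- s
  s2$V <- 3.7 * s$V + 1e6
  b1 <- detect_beats(s)
  b2 <- detect_beats(s2)
  expect_identical(attr(b1, "diastole_frames"), attr(b2, "diastole_frames"))
  expect_identical(b1$systole_frame, b2$systole_frame)
})

test_that("cycles with out-of-range rates are flagged, not dropped", {
  # 2 Hz beating with one silent stretch: the spanning cycle is slow
  t <- (0:899) / 30
  v <- 3e5 + 1e5 * sin(2 * pi * 2 * t)
  gap <- t > 10 & t < 13
  v[gap] <- 2e5
  bt <- detect_beats(series_from_V(v), hr_min_bpm = 60)
  expect_true(any(bt$flagged))
  expect_match(bt$flag_reason[bt$flagged][1], "below hr_min")
  expect_identical(nrow(bt) + 1L, length(attr(bt, "diastole_frames")))
})
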