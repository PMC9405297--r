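test_that("CSV round-trip preserves a simulated track exactly", {
  sim <- simulate_track(preset_spec("control", seed = 11, duration_s = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(sim$track, path)

  header <- readLines(path, n = 3)
  expect_match(header[1], "^scorer,")
  expect_match(header[2], "^bodyparts,")
  expect_match(header[3], "^coords,x,y,likelihood")

  back <- read_landmark_table(path, fps = sim$track$fps)
  expect_identical(back$frame_index, sim$track$frame_index)
  expect_identical(back$points, sim$track$points)
  expect_equal(unname(back$x), unname(sim$track$x), tolerance = 1e-12)
  expect_equal(unname(back$y), unname(sim$track$y), tolerance = 1e-12)
  expect_equal(unname(back$likelihood), unname(sim$track$likelihood), tolerance = 1e-12)
})

test_that("malformed tables are rejected with informative errors", {
  # 7 body parts: drop point 8's three columns
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(c("scorer", rep("m", 21)), collapse = ","),
    paste(c("bodyparts", rep(as.character(1:7), each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), 7)), collapse = ","),
    paste(c(0, rep(1, 21)), collapse = ",")
  ), path)
  expect_error(read_landmark_table(path), "missing body parts: 8",
               class = "zh_format_error")

  # non-numeric cell names the row
  sim <- simulate_track(preset_spec("control", seed = 12, duration_s = 2))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_landmark_table(sim$track, path2)
  lines <- readLines(path2)
  lines[8] <- sub("^([^,]*),[^,]*", "\\1,oops", lines[8])
  writeLines(lines, path2)
  expect_error(read_landmark_table(path2), "non-numeric value 'oops' at data row 5",
               class = "zh_parse_error")

  expect_error(read_landmark_table(withr::local_tempfile(), dialect = "hdf"),
               class = "zh_parameter_error")
  expect_error(read_landmark_table("/nonexistent/file.csv"), class = "zh_io_error")
})

test_that("writing an empty track fails", {
  sim <- simulate_track(preset_spec("control", seed = 13, duration_s = 2))
  empty <- sim$track
  empty$frame_index <- integer(0)
  empty$time_s <- numeric(0)
  empty$x <- empty$x[0, , drop = FALSE]
  empty$y <- empty$y[0, , drop = FALSE]
  empty$likelihood <- empty$likelihood[0, , drop = FALSE]
  expect_error(write_landmark_table(empty, tempfile()), class = "zh_domain_error")
})

test_that("likelihood filtering interpolates gaps as specified", {
  # cutoff 0 is an exact pass-through
  sim <- simulate_track(preset_spec("control", seed = 14, duration_s = 5))
  expect_identical(filter_by_likelihood(sim$track, 0), sim$track)

  # one low-likelihood frame between (10,10) and (12,14) -> midpoint (11,12)
  tr <- ring_track(rep(10, 3), rep(12, 3))
  tr$x[, 2] <- c(10, 0, 12); tr$y[, 2] <- c(10, 500, 14)
  tr$likelihood[2, 2] <- 0.1
  filt <- filter_by_likelihood(tr, 0.6)
  expect_equal(unname(filt$x[2, 2]), 11)
  expect_equal(unname(filt$y[2, 2]), 12)
  expect_equal(unname(filt$n_replaced["2"]), 1L)

  # leading/trailing gaps take the nearest confident value
  tr2 <- ring_track(rep(10, 4), rep(12, 4))
  tr2$x[, 3] <- c(99, 5, 6, 99)
  tr2$likelihood[c(1, 4), 3] <- 0.2
  filt2 <- filter_by_likelihood(tr2, 0.6)
  expect_equal(unname(filt2$x[1, 3]), 5)
  expect_equal(unname(filt2$x[4, 3]), 6)

  # a point with zero confident frames is unrecoverable
  tr3 <- ring_track(rep(10, 3), rep(12, 3))
  tr3$likelihood[, 5] <- 0.1
  expect_error(filter_by_likelihood(tr3, 0.6), "point 5",
               class = "zh_unrecoverable_track")
})

test_that("drop_frame policy removes whole frames with low samples", {
  tr <- ring_track(rep(10, 5), rep(12, 5))
  tr$likelihood[c(2, 4), 1] <- 0.3
  filt <- filter_by_likelihood(tr, 0.6, gap_policy = "drop_frame")
  expect_identical(filt$frame_index, c(0L, 2L, 4L))
  expect_equal(nrow(filt$x), 3)
})

test_that("filtering is idempotent and monotone in the cutoff", {
  sim <- simulate_track(preset_spec("control", seed = 15, duration_s = 10,
                                    dropout_rate = 0.05))
  once <- filter_by_likelihood(sim$track, 0.6)
  twice <- filter_by_likelihood(once, 0.6)
  expect_identical(twice, once)

  replaced <- vapply(c(0, 0.3, 0.6, 0.9),
                     function(p) sum(filter_by_likelihood(sim$track, p)$n_replaced),
                     numeric(1))
  expect_true(all(diff(replaced) >= 0))
})

test_that("interpolation reconstructs dropped-out positions near the truth", {
  # jitter-free generator: non-dropout samples are exact, so reconstruction
  # error at dropout sites comes from interpolation alone and must stay
  # below the jitter scale a noisy track would carry
  jitter_scale <- 1.5
  sim <- simulate_track(preset_spec("control", seed = 16, jitter_px = 0,
                                    dropout_rate = 0.05))
  clean <- simulate_track(preset_spec("control", seed = 16, jitter_px = 0,
                                      dropout_rate = 0))
  filt <- filter_by_likelihood(sim$track, 0.6)
  mask <- sim$truth$dropout_mask
  mae <- mean(abs(c(filt$x[mask] - clean$track$x[mask],
                    filt$y[mask] - clean$track$y[mask])))
  expect_lt(mae, jitter_scale)
})
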