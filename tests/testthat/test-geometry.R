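test_that("axis lengths are the named landmark-pair distances", {
  tr <- ring_track(rep(10, 2), rep(12, 2))
  tr$x[, 1] <- 0; tr$y[, 1] <- 0   # point 1
  tr$x[, 5] <- 3; tr$y[, 5] <- 4   # point 5: 3-4-5 triangle
  tr$x[, 3] <- 2; tr$y[, 3] <- 2   # point 3
  tr$x[, 7] <- 2; tr$y[, 7] <- 10  # point 7: axis-aligned distance 8
  ax <- suppressWarnings(axis_lengths(tr))
  expect_equal(ax$Ds, rep(5, 2))
  expect_equal(ax$Dl, rep(8, 2))
  expect_equal(ax$V, rep(pi / 6 * 8 * 25, 2))
  expect_equal(ax$centroid_x, rowMeans(tr$x))
})

test_that("a micrometer scale converts lengths and volumes", {
  tr <- ring_track(rep(10, 3), rep(12, 3))
  tr$scale_um_per_px <- 2.5
  ax <- axis_lengths(tr)
  expect_identical(attr(ax, "units"), "um")
  expect_equal(ax$Ds, rep(25, 3))
  expect_equal(ax$V, rep(pi / 6 * 30 * 25^2, 3))
})

test_that("axes warn when the short axis dominates the long axis", {
  expect_warning(axis_lengths(ring_track(rep(12, 5), rep(10, 5))),
                 "short axis exceeds long axis")
})

test_that("axes and volume are rigid-motion invariant and scale as lengths", {
  sim <- simulate_track(preset_spec("control", seed = 21, duration_s = 10))
  tr <- filter_by_likelihood(sim$track, 0.6)
  ax <- axis_lengths(tr)

  moved <- rotate_track(shift_track(tr, 37, -12), 0.7, about = c(500, 500))
  ax2 <- axis_lengths(moved)
  expect_equal(ax2$Ds, ax$Ds, tolerance = 1e-12)
  expect_equal(ax2$Dl, ax$Dl, tolerance = 1e-12)
  expect_equal(ax2$V, ax$V, tolerance = 1e-12)

  ax3 <- axis_lengths(scale_track(tr, 3))
  expect_equal(ax3$Ds, 3 * ax$Ds, tolerance = 1e-12)
  expect_equal(ax3$Dl, 3 * ax$Dl, tolerance = 1e-12)
  expect_equal(ax3$V, 27 * ax$V, tolerance = 1e-12)
})

test_that("spheroid volume matches closed forms and rejects bad axes", {
  expect_equal(spheroid_volume(2, 1), pi / 3)
  # sphere limit: Dl = Ds = d
  d <- 7.3
  expect_equal(spheroid_volume(d, d), 4 / 3 * pi * (d / 2)^3)
  # explicit prolate-spheroid form
  expect_equal(spheroid_volume(120, 80), 4 / 3 * pi * 60 * 40^2)
  expect_error(spheroid_volume(0, 1), class = "zh_domain_error")
  expect_error(spheroid_volume(1, -2), class = "zh_domain_error")
})

test_that("spheroid volume agrees with Monte-Carlo ellipsoid integration", {
  # uniform sampling in the bounding box of the ellipsoid with semi-axes
  # Dl/2, Ds/2, Ds/2; modest n here, the full-n check lives in acceptance
  set.seed(42)
  Dl <- 120; Ds <- 80
  n <- 2e5
  x <- runif(n, -Dl / 2, Dl / 2)
  y <- runif(n, -Ds / 2, Ds / 2)
  z <- runif(n, -Ds / 2, Ds / 2)
  inside <- (x / (Dl / 2))^2 + (y / (Ds / 2))^2 + (z / (Ds / 2))^2 <= 1
  v_mc <- mean(inside) * Dl * Ds^2
  expect_equal(spheroid_volume(Dl, Ds), v_mc, tolerance = 0.01)
})

test_that("centroid trajectory tracks drift and jump artifacts", {
  # static ring
  tr <- ring_track(rep(10, 5), rep(12, 5), center = c(50, 60))
  ct <- centroid_trajectory(tr)
  expect_equal(ct$centroid_x, rep(50, 5))
  expect_equal(ct$centroid_y, rep(60, 5))

  # linear slide drift: fitted centroid slope recovers the drift rate
  v_drift <- c(0.4, -0.2)
  sim <- simulate_track(preset_spec("control", seed = 22, duration_s = 20,
                                    jitter_px = 0.5, dropout_rate = 0,
                                    drift_px_per_frame = v_drift))
  ct2 <- centroid_trajectory(sim$track)
  fr <- seq_len(nrow(ct2)) - 1
  expect_equal(unname(coef(lm(ct2$centroid_x ~ fr))[2]), v_drift[1], tolerance = 0.01)
  expect_equal(unname(coef(lm(ct2$centroid_y ~ fr))[2]), v_drift[2], tolerance = 0.01)

  # sudden displacement: largest frame-to-frame centroid step is at the event
  k <- 300L
  sim3 <- simulate_track(preset_spec("control", seed = 23, duration_s = 30,
                                     jitter_px = 0.5, dropout_rate = 0,
                                     jump_events = list(list(frame = k, dx = 60, dy = -40))))
  ct3 <- centroid_trajectory(sim3$track)
  step <- sqrt(diff(ct3$centroid_x)^2 + diff(ct3$centroid_y)^2)
  expect_equal(which.max(step), k)
})
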