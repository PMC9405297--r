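# Small builders shared across tests.

# Noiseless landmark ring with given per-frame axis diameters, matching the
# simulator's landmark placement (points 3-7 along the long axis, 1-5 short).
ring_track <- function(Ds, Dl, center = c(100, 100), fps = 30, likelihood = 0.99) {
  angles <- ((1:8 - 3) %% 8) * (pi / 4)
  xs <- outer(Dl / 2, cos(angles)) + center[1]
  ys <- outer(Ds / 2, sin(angles)) + center[2]
  landmark_track(xs, ys, matrix(likelihood, length(Ds), 8), fps = fps)
}

# Axis series realizing a prescribed positive volume trace exactly.
series_from_V <- function(V, fps = 30, aspect_ratio = 1.2) {
  Ds <- (6 * V / (pi * aspect_ratio))^(1 / 3)
  axis_lengths(ring_track(Ds, aspect_ratio * Ds, fps = fps))
}

# Minimal hand-built beat table for arithmetic-level tests.
fake_beat_table <- function(EDV, ESV, Dsd, Dss, diastole_frames, fps = 30) {
  n <- length(EDV)
  ibi <- diff(diastole_frames) / fps
  out <- data.frame(
    beat = seq_len(n), diastole_frame = diastole_frames[seq_len(n)],
    systole_frame = diastole_frames[seq_len(n)] + 2L,
    EDV = EDV, ESV = ESV, Dsd = Dsd, Dss = Dss,
    IBI = ibi[seq_len(n)], inst_hr = 60 / ibi[seq_len(n)],
    flagged = FALSE, flag_reason = ""
  )
  attr(out, "fps") <- fps
  attr(out, "units") <- "px"
  attr(out, "diastole_frames") <- diastole_frames
  attr(out, "record_duration_s") <- diff(range(diastole_frames)) / fps
  class(out) <- c("beat_table", "data.frame")
  out
}

# Rotate all landmarks of a track about a point.
rotate_track <- function(track, theta, about = c(0, 0)) {
  x <- track$x - about[1]; y <- track$y - about[2]
  track$x <- cos(theta) * x - sin(theta) * y + about[1]
  track$y <- sin(theta) * x + cos(theta) * y + about[2]
  track
}

scale_track <- function(track, s) {
  track$x <- track$x * s
  track$y <- track$y * s
  track
}

shift_track <- function(track, dx, dy) {
  track$x <- track$x + dx
  track$y <- track$y + dy
  track
}
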