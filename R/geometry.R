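#' Per-frame ventricular axes and spheroid volume
#'
#' Converts the 8-point boundary ring into the two named chamber axes and the
#' spheroid ventricular volume. The short axis Ds is the Euclidean distance
#' between points 1 and 5, the long axis Dl the distance between points 3 and
#' 7; the ventricle is modelled as a prolate spheroid with polar diameter Dl
#' and equatorial diameter Ds in both transverse directions, so
#' V = (pi/6) * Dl * Ds^2 holds exactly per frame.
#'
#' @param track a filtered [landmark_track()] (all coordinates finite).
#' @return An `axis_series` data frame with columns `frame_index`, `time_s`,
#'   `Ds`, `Dl`, `V`, `centroid_x`, `centroid_y`. Lengths are in micrometers
#'   if the track carries a scale, else pixels; volumes in the cubed unit.
#'   Attributes: `fps`, `units`.
#' @export
axis_lengths <- function(track) {
  validate_landmark_track(track, require_finite = TRUE)
  i1 <- match("1", track$points); i5 <- match("5", track$points)
  i3 <- match("3", track$points); i7 <- match("7", track$points)
  Ds <- sqrt((track$x[, i1] - track$x[, i5])^2 + (track$y[, i1] - track$y[, i5])^2)
  Dl <- sqrt((track$x[, i3] - track$x[, i7])^2 + (track$y[, i3] - track$y[, i7])^2)
  cx <- rowMeans(track$x)
  cy <- rowMeans(track$y)
  units <- "px"
  if (!is.null(track$scale_um_per_px)) {
    s <- track$scale_um_per_px
    Ds <- Ds * s; Dl <- Dl * s; cx <- cx * s; cy <- cy * s
    units <- "um"
  }
  if (mean(Ds > Dl) > 0.5)
    warning("short axis exceeds long axis in more than half the frames; ",
            "check the landmark labelling (1-5 short, 3-7 long)")
  out <- data.frame(
    frame_index = track$frame_index,
    time_s = track$time_s,
    Ds = Ds, Dl = Dl,
    V = spheroid_volume(Dl, Ds),
    centroid_x = cx, centroid_y = cy
  )
  attr(out, "fps") <- track$fps
  attr(out, "units") <- units
  class(out) <- c("axis_series", "data.frame")
  out
}

#' Spheroid ventricular volume
#'
#' Volume of a prolate spheroid with long (polar) diameter `Dl` and short
#' (equatorial) diameter `Ds`: V = (pi/6) * Dl * Ds^2, equivalently
#' (4/3) * pi * (Dl/2) * (Ds/2)^2. When Dl = Ds this reduces to the sphere
#' volume (pi/6) d^3.
#'
#' @param Dl long-axis diameter (> 0).
#' @param Ds short-axis diameter (> 0), applied in both transverse directions.
#' @return Volume in cubed input units; vectorized over both arguments.
#' @export
spheroid_volume <- function(Dl, Ds) {
  if (any(!is.finite(Dl)) || any(!is.finite(Ds)) || any(Dl <= 0) || any(Ds <= 0))
    zh_domain_error("axis lengths must be finite and positive")
  (pi / 6) * Dl * Ds^2
}

#' Centroid trajectory of the landmark ring
#'
#' The per-frame mean position of all eight boundary points. Used for
#' diagnosing slide drift (a slow linear trend) and sudden displacement
#' events (a spike in frame-to-frame centroid movement); rigid whole-heart
#' motion moves the centroid but leaves axis lengths, and hence every cardiac
#' parameter, unchanged.
#'
#' @param track a filtered [landmark_track()].
#' @return A data frame with columns `frame_index`, `time_s`, `centroid_x`,
#'   `centroid_y` (pixels).
#' @export
centroid_trajectory <- function(track) {
  validate_landmark_track(track, require_finite = TRUE)
  data.frame(
    frame_index = track$frame_index,
    time_s = track$time_s,
    centroid_x = rowMeans(track$x),
    centroid_y = rowMeans(track$y)
  )
}
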