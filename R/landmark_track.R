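#' Landmark track container
#'
#' A `landmark_track` holds the per-frame positions and confidences of the
#' eight named ventricle boundary points produced by markerless pose
#' estimation, together with the acquisition timebase. Points `"1"` and `"5"`
#' span the ventricular short axis (Ds), points `"3"` and `"7"` the long axis
#' (Dl); the remaining points complete the boundary ring and contribute to the
#' centroid only.
#'
#' @param x,y numeric matrices, frames x 8, pixel coordinates (0-based pixel
#'   centers, y increasing downward).
#' @param likelihood numeric matrix, frames x 8, tracking confidence in
#'   \[0, 1\].
#' @param fps frames per second of the recording (> 0). The tracking table
#'   itself carries no timebase, so this is caller metadata; the default 30
#'   matches standard embryo videography.
#' @param frame_index integer vector of 0-based frame indices, strictly
#'   increasing. Defaults to `0:(nrow(x) - 1)`.
#' @param points character vector of the 8 point names, in ring order.
#' @param scale_um_per_px optional micrometers-per-pixel scale; `NULL` keeps
#'   all lengths in pixels.
#'
#' @return An object of class `landmark_track`: a list with elements
#'   `frame_index`, `time_s`, `fps`, `points`, `x`, `y`, `likelihood`,
#'   `scale_um_per_px`, and `n_replaced` (per-point count of samples replaced
#'   by likelihood filtering; zeros for a fresh track).
#' @seealso [read_landmark_table()], [filter_by_likelihood()], [axis_lengths()]
#' @export
landmark_track <- function(x, y, likelihood, fps = 30,
                           frame_index = NULL,
                           points = as.character(1:8),
                           scale_um_per_px = NULL) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (is.null(frame_index)) frame_index <- seq_len(nrow(x)) - 1L
  frame_index <- as.integer(frame_index)
  track <- structure(list(
    frame_index = frame_index,
    time_s = frame_index / fps,
    fps = fps,
    points = as.character(points),
    x = x, y = y, likelihood = likelihood,
    scale_um_per_px = scale_um_per_px,
    n_replaced = stats::setNames(integer(length(points)), points)
  ), class = "landmark_track")
  validate_landmark_track(track)
}

validate_landmark_track <- function(track, require_finite = FALSE) {
  p <- track$points
  if (length(p) != 8L || anyDuplicated(p))
    zh_format_error(sprintf("a landmark track needs exactly 8 unique point names, got: %s",
                            paste(p, collapse = ", ")))
  n <- length(track$frame_index)
  for (f in c("x", "y", "likelihood")) {
    m <- track[[f]]
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 8L)
      zh_format_error(sprintf("'%s' must be a %d x 8 numeric matrix", f, n))
  }
  if (n > 1 && any(diff(track$frame_index) <= 0L))
    zh_format_error("frame_index must be strictly increasing with no duplicates")
  lk <- track$likelihood
  if (any(!is.finite(lk)) || any(lk < 0) || any(lk > 1))
    zh_format_error("likelihood values must be finite and within [0, 1]")
  if (!is.numeric(track$fps) || track$fps <= 0)
    zh_parameter_error("fps must be a positive number")
  if (require_finite && (any(!is.finite(track$x)) || any(!is.finite(track$y)))) {
    bad <- which(!is.finite(track$x) | !is.finite(track$y), arr.ind = TRUE)
    zh_contract_error(sprintf("non-finite coordinates at frame %d, point %s",
                              track$frame_index[bad[1, 1]], track$points[bad[1, 2]]))
  }
  colnames(track$x) <- colnames(track$y) <- colnames(track$likelihood) <- p
  track
}

#' @export
print.landmark_track <- function(x, ...) {
  n <- length(x$frame_index)
  cat(sprintf("<landmark_track> %d frames @ %g fps (%.1f s), 8 points [%s]\n",
              n, x$fps, n / x$fps, paste(x$points, collapse = " ")))
  if (!is.null(x$scale_um_per_px))
    cat(sprintf("  scale: %g um/px\n", x$scale_um_per_px))
  if (any(x$n_replaced > 0))
    cat("  filtered samples per point:",
        paste(sprintf("%s=%d", names(x$n_replaced), x$n_replaced), collapse = " "), "\n")
  invisible(x)
}

#' Number of frames in a landmark track
#' @param track a `landmark_track`.
#' @return integer frame count.
#' @export
n_frames <- function(track) length(track$frame_index)
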