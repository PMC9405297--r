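#' Fit the cardiac physiology model to a landmark track
#'
#' The central estimator of the package: takes a raw landmark track (or the
#' path of a tracking table) and runs the full analysis chain --
#' likelihood filtering, axis and spheroid-volume geometry, beat
#' segmentation, the seven-parameter cardiac panel and Poincare
#' heart-rate-variability indices -- returning a single fitted object.
#'
#' @param track a [landmark_track()], or a path passed to
#'   [read_landmark_table()].
#' @param fps frames per second (used only when `track` is a path).
#' @param scale_um_per_px optional micrometers-per-pixel scale (path input).
#' @param p_cutoff likelihood cutoff for [filter_by_likelihood()].
#' @param gap_policy gap handling, `"interpolate"` or `"drop_frame"`.
#' @param smooth_window moving-average window (frames) for peak detection.
#' @param min_prominence_frac,hr_max_bpm,hr_min_bpm see [detect_beats()].
#' @param sf_denominator shortening-fraction denominator convention, see
#'   [compute_panel()].
#' @param normalization optional reference volume for normalized stroke
#'   volume.
#' @param confidence Poincare ellipse confidence level (default 0.95).
#' @return An object of class `heart_scan`: a list with elements `track`
#'   (filtered), `axes` (`axis_series`), `beats` (`beat_table`), `panel`
#'   (`cardiac_panel`), `hrv` (`poincare_result`, or `NULL` if fewer than 4
#'   beats), `params`, and `call`. Supported methods: `print`, `summary`,
#'   `coef`, `plot`, `residuals`, `simulate`.
#'
#' @examples
#' sim <- simulate_track(preset_spec("control", seed = 1))
#' fit <- heart_scan(sim$track)
#' coef(fit)
#' summary(fit)
#' @export
heart_scan <- function(track, fps = 30, scale_um_per_px = NULL,
                       p_cutoff = 0.6, gap_policy = c("interpolate", "drop_frame"),
                       smooth_window = 5L, min_prominence_frac = 0.3,
                       hr_max_bpm = 400, hr_min_bpm = 40,
                       sf_denominator = c("systolic", "diastolic"),
                       normalization = NULL, confidence = 0.95) {
  gap_policy <- match.arg(gap_policy)
  sf_denominator <- match.arg(sf_denominator)
  if (is.character(track))
    track <- read_landmark_table(track, fps = fps, scale_um_per_px = scale_um_per_px)
  if (!inherits(track, "landmark_track"))
    zh_parameter_error("track must be a landmark_track or a file path")

  filtered <- filter_by_likelihood(track, p_cutoff = p_cutoff, gap_policy = gap_policy)
  axes <- axis_lengths(filtered)
  beats <- detect_beats(axes, min_prominence_frac = min_prominence_frac,
                        hr_max_bpm = hr_max_bpm, hr_min_bpm = hr_min_bpm,
                        smooth_window = smooth_window)
  panel <- compute_panel(beats, sf_denominator = sf_denominator,
                         normalization = normalization)
  ibis <- beat_intervals(beats)
  hrv <- if (length(ibis) >= 3L) poincare(ibis, confidence = confidence) else NULL

  structure(list(
    track = filtered, axes = axes, beats = beats, panel = panel, hrv = hrv,
    params = list(p_cutoff = p_cutoff, gap_policy = gap_policy,
                  smooth_window = smooth_window,
                  min_prominence_frac = min_prominence_frac,
                  hr_max_bpm = hr_max_bpm, hr_min_bpm = hr_min_bpm,
                  sf_denominator = sf_denominator,
                  normalization = normalization, confidence = confidence),
    call = match.call()
  ), class = "heart_scan")
}

#' @export
print.heart_scan <- function(x, ...) {
  cat("Cardiac physiology fit (heart_scan)\n")
  cat(sprintf("  %d frames @ %g fps, %d cardiac cycles%s\n",
              n_frames(x$track), x$track$fps, nrow(x$beats),
              if (any(x$beats$flagged)) sprintf(" (%d flagged)", sum(x$beats$flagged)) else ""))
  cat(sprintf("  heart rate %.1f bpm, EF %.1f%%, SF %.1f%%\n",
              x$panel$heart_rate, x$panel$EF, x$panel$SF))
  invisible(x)
}

#' @export
summary.heart_scan <- function(object, ...) {
  structure(list(
    panel = object$panel, hrv = object$hrv,
    n_frames = n_frames(object$track), fps = object$track$fps,
    n_replaced = object$track$n_replaced,
    n_flagged = sum(object$beats$flagged),
    params = object$params
  ), class = "summary.heart_scan")
}

#' @export
print.summary.heart_scan <- function(x, ...) {
  cat(sprintf("heart_scan summary: %d frames @ %g fps\n", x$n_frames, x$fps))
  if (sum(x$n_replaced) > 0)
    cat(sprintf("  low-likelihood samples replaced: %d (p_cutoff %.2f)\n",
                sum(x$n_replaced), x$params$p_cutoff))
  if (x$n_flagged > 0)
    cat(sprintf("  %d cycle(s) flagged as physiologically out of range\n", x$n_flagged))
  print(x$panel)
  if (!is.null(x$hrv)) print(x$hrv)
  invisible(x)
}

#' Extract the cardiac parameters of a fit
#'
#' @param object a `heart_scan`.
#' @param ... unused.
#' @return Named numeric vector: `heart_rate` (bpm), `EDV`, `ESV`, `SV`
#'   (volume units), `CO` (volume/min), `EF`, `SF` (percent), `sd1`, `sd2`
#'   (seconds; `NA` when too few beats for HRV).
#' @export
coef.heart_scan <- function(object, ...) {
  p <- object$panel
  c(heart_rate = p$heart_rate, EDV = p$EDV, ESV = p$ESV, SV = p$SV,
    CO = p$CO, EF = p$EF, SF = p$SF,
    sd1 = if (is.null(object$hrv)) NA_real_ else object$hrv$sd1,
    sd2 = if (is.null(object$hrv)) NA_real_ else object$hrv$sd2)
}

#' Diagnostic plots for a cardiac fit
#'
#' Panel 1: the volume trace with detected diastolic (peaks) and systolic
#' (troughs) frames. Panel 2: the centroid trajectory, which exposes slide
#' drift and sudden displacement events. Panel 3: the Poincare scatter with
#' its confidence ellipse.
#'
#' @param x a `heart_scan`.
#' @param which subset of `1:3` selecting the panels.
#' @param ... further graphical arguments (passed to the volume-trace plot).
#' @return `x`, invisibly.
#' @export
plot.heart_scan <- function(x, which = 1:3, ...) {
  if (1 %in% which) {
    u <- attr(x$axes, "units")
    graphics::plot(x$axes$time_s, x$axes$V, type = "l", col = "grey40",
                   xlab = "time (s)", ylab = sprintf("ventricular volume (%s^3)", u),
                   main = "Volume trace with detected beats", ...)
    di <- match(x$beats$diastole_frame, x$axes$frame_index)
    sy <- match(x$beats$systole_frame, x$axes$frame_index)
    graphics::points(x$axes$time_s[di], x$axes$V[di], col = "firebrick", pch = 16)
    graphics::points(x$axes$time_s[sy], x$axes$V[sy], col = "steelblue", pch = 17)
  }
  if (2 %in% which) {
    graphics::plot(x$axes$centroid_x, x$axes$centroid_y, type = "l", asp = 1,
                   xlab = "centroid x (px)", ylab = "centroid y (px)",
                   main = "Centroid trajectory")
  }
  if (3 %in% which && !is.null(x$hrv)) plot(x$hrv)
  invisible(x)
}

#' Residual volume fluctuation of a fit
#'
#' The unsmoothed minus the moving-average-smoothed volume trace: the
#' high-frequency component the beat detector is designed to ignore, useful
#' for judging tracking-noise levels.
#'
#' @param object a `heart_scan`.
#' @param ... unused.
#' @return Numeric vector, one value per frame.
#' @export
residuals.heart_scan <- function(object, ...) {
  sm <- smooth_volume(object$axes, object$params$smooth_window)
  object$axes$V - sm$V
}

#' Simulate synthetic recordings matching a fitted heart
#'
#' Builds a [synthetic_spec()] from the fitted heart rate, volume extremes
#' (per-beat mean EDV/ESV) and interval variability, and generates new
#' landmark tracks from it — a parametric-bootstrap-style check that the
#' pipeline recovers what it estimated.
#'
#' @param object a `heart_scan` (volumes must be in pixel units).
#' @param nsim number of tracks to simulate.
#' @param seed RNG seed for the first replicate; replicate i uses `seed + i - 1`.
#' @param ... overrides forwarded to [synthetic_spec()].
#' @return A list of `nsim` results from [simulate_track()].
#' @export
simulate.heart_scan <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$panel
  ibis <- beat_intervals(object$beats)
  ar1 <- if (length(ibis) >= 10) max(min(stats::cor(ibis[-1], ibis[-length(ibis)]), 0.95), 0) else 0
  base <- list(
    duration_s = n_frames(object$track) / object$track$fps,
    fps = object$track$fps,
    hr_bpm = p$heart_rate,
    rr_sd_s = stats::sd(ibis),
    rr_ar1 = ar1,
    EDV0 = p$EDV, ESV0 = p$ESV
  )
  lapply(seq_len(nsim), function(i) {
    args <- utils::modifyList(base, list(...))
    args$seed <- if (is.null(seed)) NULL else seed + i - 1L
    simulate_track(do.call(synthetic_spec, args))
  })
}
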