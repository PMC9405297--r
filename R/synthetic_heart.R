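#' Specification for a synthetic beating-heart recording
#'
#' Defines the generative model behind [simulate_track()]: a prolate-spheroid
#' ventricle whose volume follows an asymmetric raised-cosine pulse between
#' end-diastolic volume `EDV0` and end-systolic volume `ESV0`, beating with
#' AR(1)-jittered inter-beat intervals, observed through eight boundary
#' landmarks subject to tracking jitter, likelihood dropouts, slide drift and
#' sudden displacement events.
#'
#' @param duration_s recording length in seconds (default 60, a standard
#'   1-minute embryo recording).
#' @param fps frame rate (default 30).
#' @param hr_bpm mean heart rate in beats per minute.
#' @param rr_sd_s stationary SD of the inter-beat-interval jitter, seconds.
#' @param rr_ar1 lag-1 autocorrelation of the interval process, in (-1, 1);
#'   positive values separate long-term (sd2) from instantaneous (sd1)
#'   variability.
#' @param EDV0,ESV0 waveform extreme volumes in cubic pixels; `EDV0 > ESV0 > 0`.
#' @param aspect_ratio Dl / Ds (default 1.2: a primarily spherical, slightly
#'   elongated ovoid ventricle).
#' @param systolic_fraction fraction of the cycle spent contracting
#'   (default 0.35).
#' @param center_xy ventricle center in pixels.
#' @param jitter_px per-landmark, per-frame Gaussian tracking noise SD, pixels.
#' @param drift_px_per_frame length-2 linear slide-drift vector, px/frame.
#' @param jump_events list of `list(frame =, dx =, dy =)` sudden whole-heart
#'   displacements applied from `frame` onward.
#' @param dropout_rate fraction of (frame, point) samples given sub-cutoff
#'   likelihood and a corrupted position.
#' @param seed RNG seed; same spec + same seed reproduces the track exactly.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(duration_s = 60, fps = 30, hr_bpm = 150,
                           rr_sd_s = 0.05, rr_ar1 = 0.4,
                           EDV0 = 4e5, ESV0 = 2e5,
                           aspect_ratio = 1.2, systolic_fraction = 0.35,
                           center_xy = c(960, 540), jitter_px = 1,
                           drift_px_per_frame = c(0, 0),
                           jump_events = list(), dropout_rate = 0.02,
                           seed = NULL) {
  spec <- structure(as.list(environment()), class = "synthetic_spec")
  if (!(EDV0 > ESV0 && ESV0 > 0))
    zh_parameter_error("need EDV0 > ESV0 > 0")
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    zh_parameter_error("systolic_fraction must lie strictly between 0 and 1")
  if (abs(rr_ar1) >= 1)
    zh_parameter_error("rr_ar1 must lie in (-1, 1)")
  if (fps * 60 / hr_bpm < 6)
    zh_parameter_error(sprintf(
      "unresolvable beat: %.1f frames per beat at %g bpm and %g fps (need >= 6)",
      fps * 60 / hr_bpm, hr_bpm, fps))
  if (duration_s <= 0 || fps <= 0)
    zh_parameter_error("duration_s and fps must be positive")
  spec
}

#' Named simulation presets for treatment scenarios
#'
#' `control` encodes nominal 2-3 dpf embryo values. `ethanol_like` lowers
#' heart rate and both volume extremes (an edema-like, globally depressed
#' heart). `ponatinib_like` additionally shrinks the ejection amplitude
#' (lower ejection and shortening fraction) and inflates interval jitter and
#' its autocorrelation (arrhythmia). Magnitudes are simulator conventions
#' chosen for directional realism, not measurements; only effect directions
#' are meaningful.
#'
#' @param name one of `"control"`, `"ethanol_like"`, `"ponatinib_like"`.
#' @param ... overrides passed on to [synthetic_spec()] (e.g. `seed`).
#' @return A `synthetic_spec`.
#' @export
preset_spec <- function(name = c("control", "ethanol_like", "ponatinib_like"), ...) {
  if (!is.character(name) || length(name) != 1L ||
      !name %in% c("control", "ethanol_like", "ponatinib_like"))
    zh_parameter_error(sprintf("unknown preset '%s'", paste(name, collapse = ", ")))
  base <- switch(name,
    control = list(hr_bpm = 150, EDV0 = 4e5, ESV0 = 2e5,
                   rr_sd_s = 0.05, rr_ar1 = 0.4),
    ethanol_like = list(hr_bpm = 120, EDV0 = 3.2e5, ESV0 = 1.8e5,
                        rr_sd_s = 0.05, rr_ar1 = 0.4),
    ponatinib_like = list(hr_bpm = 110, EDV0 = 2.8e5, ESV0 = 1.96e5,
                          rr_sd_s = 0.10, rr_ar1 = 0.6)
  )
  do.call(synthetic_spec, utils::modifyList(base, list(...)))
}

#' Simulate a landmark track of a pulsating ventricle
#'
#' Generates per-frame positions of the eight boundary landmarks of a
#' spheroid ventricle of oscillating volume, plus the full ground truth
#' needed to validate every downstream stage.
#'
#' The generative steps: (1) inter-beat intervals are `60 / hr_bpm` plus a
#' stationary AR(1) Gaussian process (SD `rr_sd_s`, coefficient `rr_ar1`),
#' floored at 6 frames; the first diastolic peak is anchored half an interval
#' into the record so every true peak is an interior maximum. (2) Within each
#' beat the volume follows a raised-cosine pulse from `EDV0` down to `ESV0`
#' over `systolic_fraction` of the cycle and back. (3) Per frame,
#' `Ds = (6 V / (pi * aspect_ratio))^(1/3)` and `Dl = aspect_ratio * Ds`, so
#' recomputing the spheroid volume from the landmark ring returns `V`
#' exactly in the noiseless case. (4) The eight landmarks sit at 45-degree
#' increments on the ellipse with semi-axes Dl/2 (points 3-7 direction) and
#' Ds/2 (points 1-5 direction), centered at `center_xy` plus accumulated
#' drift and jump displacements. (5) I.i.d. Gaussian jitter is added per
#' landmark per frame. (6) A `dropout_rate` fraction of samples get
#' likelihood below any usual cutoff and a grossly corrupted position.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `track` (a [landmark_track()]) and `truth`, a list of
#'   `beat_frames`, `beat_times_s` (exact peak times), `ibis` (exact
#'   intervals, seconds), `hr_bpm` (mean instantaneous rate of the realized
#'   intervals), `EDV`, `ESV` (waveform extremes), `sd1`, `sd2` (Poincare
#'   indices of the realized interval sequence), `V` (noiseless per-frame
#'   volume), and `dropout_mask`.
#' @export
simulate_track <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    zh_parameter_error("spec must be a synthetic_spec")
  if (!is.null(spec$seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
  }

  n <- round(spec$duration_s * spec$fps)
  t_frames <- (seq_len(n) - 1L) / spec$fps
  ibi_mean <- 60 / spec$hr_bpm
  ibi_floor <- 6 / spec$fps

  # AR(1) interval noise, stationary at SD rr_sd_s
  m <- ceiling(spec$duration_s / ibi_mean) + 10L
  eps <- numeric(m)
  if (spec$rr_sd_s > 0) {
    eps[1] <- stats::rnorm(1, 0, spec$rr_sd_s)
    innov_sd <- spec$rr_sd_s * sqrt(1 - spec$rr_ar1^2)
    for (i in seq_len(m - 1L))
      eps[i + 1L] <- spec$rr_ar1 * eps[i] + stats::rnorm(1, 0, innov_sd)
  }
  ibi_all <- pmax(ibi_mean + eps, ibi_floor)
  peaks <- 0.5 * ibi_all[1] + c(0, cumsum(ibi_all[-m]))
  while (peaks[length(peaks)] < spec$duration_s + ibi_mean) {
    extra <- max(ibi_mean, ibi_floor)
    peaks <- c(peaks, peaks[length(peaks)] + extra)
    ibi_all <- c(ibi_all, extra)
  }
  peaks_ext <- c(peaks[1] - ibi_all[1], peaks)  # virtual pre-record peak

  # raised-cosine volume pulse, asymmetric in systolic_fraction
  j <- findInterval(t_frames, peaks_ext)
  phase <- (t_frames - peaks_ext[j]) / (peaks_ext[j + 1L] - peaks_ext[j])
  sf <- spec$systolic_fraction
  amp <- spec$EDV0 - spec$ESV0
  V <- ifelse(phase < sf,
              spec$ESV0 + amp * (1 + cos(pi * phase / sf)) / 2,
              spec$ESV0 + amp * (1 - cos(pi * (phase - sf) / (1 - sf))) / 2)

  Ds <- (6 * V / (pi * spec$aspect_ratio))^(1 / 3)
  Dl <- spec$aspect_ratio * Ds

  # landmarks at 45-degree increments; 3-7 along the long axis, 1-5 short
  angles <- ((1:8 - 3) %% 8) * (pi / 4)
  xs <- outer(Dl / 2, cos(angles))
  ys <- outer(Ds / 2, sin(angles))

  offset_x <- spec$center_xy[1] + spec$drift_px_per_frame[1] * (seq_len(n) - 1L)
  offset_y <- spec$center_xy[2] + spec$drift_px_per_frame[2] * (seq_len(n) - 1L)
  for (ev in spec$jump_events) {
    from <- ev$frame + 1L  # ev$frame is 0-based
    if (from <= n) {
      offset_x[from:n] <- offset_x[from:n] + ev$dx
      offset_y[from:n] <- offset_y[from:n] + ev$dy
    }
  }
  xs <- xs + offset_x
  ys <- ys + offset_y

  if (spec$jitter_px > 0) {
    xs <- xs + matrix(stats::rnorm(n * 8L, 0, spec$jitter_px), n, 8L)
    ys <- ys + matrix(stats::rnorm(n * 8L, 0, spec$jitter_px), n, 8L)
  }

  lk <- matrix(0.99, n, 8L)
  drop_mask <- matrix(FALSE, n, 8L)
  if (spec$dropout_rate > 0) {
    n_drop <- round(spec$dropout_rate * n * 8L)
    if (n_drop > 0) {
      drop_idx <- sample.int(n * 8L, n_drop)
      drop_mask[drop_idx] <- TRUE
      lk[drop_idx] <- stats::runif(n_drop, 0, 0.3)
      corrupt_sd <- 0.25 * (6 * spec$EDV0 / (pi * spec$aspect_ratio))^(1 / 3)
      xs[drop_idx] <- xs[drop_idx] + stats::rnorm(n_drop, 0, corrupt_sd)
      ys[drop_idx] <- ys[drop_idx] + stats::rnorm(n_drop, 0, corrupt_sd)
    }
  }

  track <- landmark_track(xs, ys, lk, fps = spec$fps)

  in_rec <- peaks >= 0 & peaks <= t_frames[n]
  peak_t <- peaks[in_rec]
  ibis <- diff(peak_t)
  pc <- if (length(ibis) >= 3L) poincare(ibis) else list(sd1 = NA_real_, sd2 = NA_real_)
  truth <- list(
    beat_frames = as.integer(round(peak_t * spec$fps)),
    beat_times_s = peak_t,
    ibis = ibis,
    hr_bpm = mean(60 / ibis),
    EDV = spec$EDV0,
    ESV = spec$ESV0,
    sd1 = pc$sd1,
    sd2 = pc$sd2,
    V = V,
    dropout_mask = drop_mask
  )
  list(track = track, truth = truth)
}
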