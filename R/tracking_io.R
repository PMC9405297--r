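#' Read a landmark tracking table
#'
#' Parses the standard pose-estimation CSV layout: three header rows (scorer;
#' body parts, each repeated three times; coords cycling x, y, likelihood) and
#' one leading frame-index column. Exactly eight body parts are required.
#'
#' @param path path to the table.
#' @param dialect table dialect; only `"csv3header"` (the three-header-row CSV
#'   written by pose-estimation pipelines) is supported.
#' @param fps frames per second of the recording; the table carries no
#'   timebase, so this is caller metadata (default 30).
#' @param scale_um_per_px optional micrometers-per-pixel scale.
#'
#' @return A [landmark_track()] whose point order follows the header's
#'   body-part order.
#' @export
read_landmark_table <- function(path, dialect = c("csv3header", "hdf"),
                                fps = 30, scale_um_per_px = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "hdf")
    zh_parameter_error("the 'hdf' dialect is not supported by this build; use 'csv3header'")
  if (!file.exists(path))
    zh_io_error(sprintf("file not found: %s", path))

  header <- readLines(path, n = 3L)
  if (length(header) < 3L)
    zh_format_error("expected 3 header rows (scorer / bodyparts / coords)")
  split_row <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  bp_row <- split_row(header[2])[-1]
  coords_row <- split_row(header[3])[-1]
  parts <- unique(bp_row)

  expected <- as.character(1:8)
  if (!setequal(parts, expected) || length(parts) != 8L) {
    missing <- setdiff(expected, parts)
    extra <- setdiff(parts, expected)
    msg <- c(
      if (length(missing)) sprintf("missing body parts: %s", paste(missing, collapse = ", ")),
      if (length(extra)) sprintf("unexpected body parts: %s", paste(extra, collapse = ", "))
    )
    zh_format_error(paste(c("malformed body-part header;", msg), collapse = " "))
  }
  if (length(bp_row) != 24L || !all(bp_row == rep(parts, each = 3L)))
    zh_format_error("each body part must contribute exactly 3 consecutive columns")
  if (!all(coords_row == rep(c("x", "y", "likelihood"), times = 8L)))
    zh_format_error("coords header row must cycle x, y, likelihood per body part")

  raw <- utils::read.csv(path, skip = 3L, header = FALSE,
                         colClasses = "character", blank.lines.skip = TRUE)
  if (ncol(raw) != 25L)
    zh_format_error(sprintf("expected 25 data columns (index + 8 x 3), got %d", ncol(raw)))
  num <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L)
  bad <- which(is.na(num) & !(raw == "" | toupper(as.matrix(raw)) == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0)
    zh_parse_error(sprintf("non-numeric value '%s' at data row %d, column %d",
                           as.matrix(raw)[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2]))

  idx <- as.integer(num[, 1])
  xs <- num[, 1 + seq(1, 24, by = 3), drop = FALSE]
  ys <- num[, 1 + seq(2, 24, by = 3), drop = FALSE]
  lk <- num[, 1 + seq(3, 24, by = 3), drop = FALSE]
  landmark_track(xs, ys, lk, fps = fps, frame_index = idx, points = parts,
                 scale_um_per_px = scale_um_per_px)
}

#' Write a landmark tracking table
#'
#' Serializes a track in the three-header-row CSV dialect so it can be read
#' back by [read_landmark_table()] with bitwise-equal frame indices and
#' value-equal coordinates.
#'
#' @param track a [landmark_track()] with at least one frame.
#' @param path output path.
#' @param dialect only `"csv3header"` is supported.
#' @param scorer name placed in the scorer header row.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(track, path, dialect = c("csv3header", "hdf"),
                                 scorer = "zebraheart") {
  dialect <- match.arg(dialect)
  if (dialect == "hdf")
    zh_parameter_error("the 'hdf' dialect is not supported by this build; use 'csv3header'")
  if (n_frames(track) == 0L)
    zh_domain_error("cannot write an empty track (0 frames)")

  con <- tryCatch(file(path, "w"), error = function(e)
    zh_io_error(sprintf("cannot open '%s' for writing: %s", path, conditionMessage(e))))
  on.exit(close(con))

  writeLines(c(
    paste(c("scorer", rep(scorer, 24L)), collapse = ","),
    paste(c("bodyparts", rep(track$points, each = 3L)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), times = 8L)), collapse = ",")
  ), con)
  body <- matrix(NA_real_, nrow = n_frames(track), ncol = 24L)
  body[, seq(1, 24, by = 3)] <- track$x
  body[, seq(2, 24, by = 3)] <- track$y
  body[, seq(3, 24, by = 3)] <- track$likelihood
  lines <- apply(cbind(format(track$frame_index, scientific = FALSE, trim = TRUE),
                       format(body, digits = 17, scientific = FALSE, trim = TRUE)),
                 1L, paste, collapse = ",")
  writeLines(lines, con)
  invisible(path)
}

#' Replace or drop low-confidence landmark samples
#'
#' Every (frame, point) sample whose tracking likelihood falls below
#' `p_cutoff` is treated as unreliable. Under `gap_policy = "interpolate"`
#' the sample's coordinates are replaced by linear interpolation between the
#' nearest flanking confident frames of the same point; leading and trailing
#' gaps take the nearest confident value (no extrapolation). Under
#' `"drop_frame"` any frame containing an unreliable sample is removed
#' entirely. The per-point count of replaced samples is accumulated in the
#' returned track's `n_replaced` field.
#'
#' A cutoff of 0 is an exact pass-through. The operation is idempotent:
#' replaced samples get likelihood 1, so a second pass at the same cutoff
#' changes nothing.
#'
#' @param track a [landmark_track()].
#' @param p_cutoff likelihood threshold in \[0, 1\]; the conventional
#'   pose-estimation default is 0.6.
#' @param gap_policy `"interpolate"` (default) or `"drop_frame"`.
#' @return A filtered `landmark_track` with all retained coordinates finite.
#' @export
filter_by_likelihood <- function(track, p_cutoff = 0.6,
                                 gap_policy = c("interpolate", "drop_frame")) {
  gap_policy <- match.arg(gap_policy)
  if (!is.numeric(p_cutoff) || length(p_cutoff) != 1L || p_cutoff < 0 || p_cutoff > 1)
    zh_parameter_error("p_cutoff must be a single value in [0, 1]")
  if (p_cutoff == 0) return(track)

  low <- track$likelihood < p_cutoff
  for (j in seq_along(track$points)) {
    if (all(low[, j]))
      zh_unrecoverable_track(sprintf(
        "point %s is confident in zero frames at p_cutoff=%g", track$points[j], p_cutoff))
  }

  if (gap_policy == "drop_frame") {
    keep <- !apply(low, 1L, any)
    if (!any(keep))
      zh_unrecoverable_track("all frames contain a sample below the cutoff")
    out <- track
    out$frame_index <- track$frame_index[keep]
    out$time_s <- track$time_s[keep]
    out$x <- track$x[keep, , drop = FALSE]
    out$y <- track$y[keep, , drop = FALSE]
    out$likelihood <- track$likelihood[keep, , drop = FALSE]
    out$n_replaced <- out$n_replaced + colSums(low)
    return(validate_landmark_track(out, require_finite = TRUE))
  }

  out <- track
  fi <- track$frame_index
  for (j in seq_along(track$points)) {
    bad <- low[, j]
    if (!any(bad)) next
    good <- which(!bad)
    # approx with rule = 2 gives linear interpolation inside the record and
    # nearest-confident-value extension at the edges
    out$x[bad, j] <- stats::approx(fi[good], track$x[good, j], xout = fi[bad],
                                   method = "linear", rule = 2)$y
    out$y[bad, j] <- stats::approx(fi[good], track$y[good, j], xout = fi[bad],
                                   method = "linear", rule = 2)$y
    out$likelihood[bad, j] <- 1
    out$n_replaced[j] <- out$n_replaced[j] + sum(bad)
  }
  validate_landmark_track(out, require_finite = TRUE)
}
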