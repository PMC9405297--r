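#' Seven-parameter cardiac panel from a beat table
#'
#' Aggregates per-cycle measurements into the record-level panel:
#' \itemize{
#'   \item stroke volume SV_i = EDV_i - ESV_i (volume ejected per beat);
#'   \item ejection fraction EF_i = SV_i / EDV_i x 100 (percent);
#'   \item shortening fraction SF_i = (Dsd_i - Dss_i) / Dss_i x 100 (percent),
#'     with the systolic short-axis diameter in the denominator -- the form
#'     used throughout this workflow; the conventional echocardiographic
#'     definition divides by the diastolic diameter Dsd instead and is
#'     available via `sf_denominator = "diastolic"`;
#'   \item cardiac output CO = mean(SV_i) x heart rate (volume per minute).
#' }
#' Panel values are per-cycle means; the per-cycle table is retained so a
#' single-beat readout remains recoverable.
#'
#' @param table a `beat_table` from [detect_beats()] with at least one
#'   complete cycle.
#' @param hr heart rate in bpm; defaults to the instantaneous-rate average of
#'   the table's own inter-beat intervals (see [heart_rate()]).
#' @param sf_denominator `"systolic"` (Dss, the default) or `"diastolic"`
#'   (Dsd, the conventional definition).
#' @param normalization optional reference volume; if given, `SV_normalized
#'   = SV / normalization` is reported in addition.
#' @return A `cardiac_panel` list: `heart_rate`, `heart_rate_count_based`,
#'   `EDV`, `ESV`, `SV`, `CO`, `EF`, `SF`, `n_beats`, `units`,
#'   `sf_denominator`, optional `SV_normalized`, and `per_beat` (per-cycle
#'   values of EDV, ESV, SV, EF, SF).
#' @export
compute_panel <- function(table, hr = NULL,
                          sf_denominator = c("systolic", "diastolic"),
                          normalization = NULL) {
  sf_denominator <- match.arg(sf_denominator)
  if (nrow(table) < 1L)
    zh_insufficient_beats("need at least one complete cardiac cycle")
  inverted <- which(table$ESV >= table$EDV)
  if (length(inverted))
    zh_domain_error(sprintf("ESV >= EDV in cycle(s) %s (inverted cycle)",
                            paste(inverted, collapse = ", ")))
  if (any(table$Dss <= 0) || any(table$Dsd <= 0))
    zh_domain_error("short-axis diameters must be positive")

  if (is.null(hr)) {
    hr_both <- heart_rate(beat_intervals(table))
    hr <- hr_both$bpm
    hr_count <- hr_both$bpm_count_based
  } else {
    if (!is.numeric(hr) || hr <= 0) zh_parameter_error("hr must be a positive number")
    hr_count <- NA_real_
  }

  sv <- table$EDV - table$ESV
  ef <- sv / table$EDV * 100
  sf <- if (sf_denominator == "systolic") {
    (table$Dsd - table$Dss) / table$Dss * 100
  } else {
    (table$Dsd - table$Dss) / table$Dsd * 100
  }

  panel <- list(
    heart_rate = hr,
    heart_rate_count_based = hr_count,
    EDV = mean(table$EDV),
    ESV = mean(table$ESV),
    SV = mean(sv),
    CO = mean(sv) * hr,
    EF = mean(ef),
    SF = mean(sf),
    n_beats = nrow(table),
    units = attr(table, "units"),
    sf_denominator = sf_denominator,
    per_beat = data.frame(beat = table$beat, EDV = table$EDV, ESV = table$ESV,
                          SV = sv, EF = ef, SF = sf)
  )
  if (!is.null(normalization)) {
    if (!is.numeric(normalization) || normalization <= 0)
      zh_parameter_error("normalization must be a positive reference volume")
    panel$SV_normalized <- panel$SV / normalization
  }
  class(panel) <- "cardiac_panel"
  panel
}

#' @export
print.cardiac_panel <- function(x, ...) {
  u <- x$units
  cat("Cardiac panel (", x$n_beats, " beats)\n", sep = "")
  cat(sprintf("  heart rate       %8.1f bpm\n", x$heart_rate))
  cat(sprintf("  EDV              %8.4g %s^3\n", x$EDV, u))
  cat(sprintf("  ESV              %8.4g %s^3\n", x$ESV, u))
  cat(sprintf("  stroke volume    %8.4g %s^3\n", x$SV, u))
  cat(sprintf("  cardiac output   %8.4g %s^3/min\n", x$CO, u))
  cat(sprintf("  ejection fraction%8.1f %%\n", x$EF))
  cat(sprintf("  shortening frac. %8.1f %% (denominator: D%s)\n", x$SF,
              if (x$sf_denominator == "systolic") "ss" else "sd"))
  if (!is.null(x$SV_normalized))
    cat(sprintf("  normalized SV    %8.4g\n", x$SV_normalized))
  invisible(x)
}

#' Serialize a cardiac panel (with optional HRV result) to JSON
#'
#' @param panel a `cardiac_panel`.
#' @param poincare optional `poincare_result` to embed under `hrv`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
panel_to_json <- function(panel, poincare = NULL, path = NULL) {
  x <- unclass(panel)
  x$per_beat <- NULL
  if (!is.null(poincare)) {
    x$hrv <- list(sd1 = poincare$sd1, sd2 = poincare$sd2,
                  mean_ibi = poincare$center[1], confidence = poincare$confidence,
                  n_pairs = nrow(poincare$pairs))
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
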