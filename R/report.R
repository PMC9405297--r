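#' Batch-analyze tracking tables into a report bundle
#'
#' Runs [heart_scan()] over a set of tracking tables (or pre-built
#' `landmark_track` objects) and writes, per input: the axis series CSV
#' (`<name>_axes.csv`), the per-cycle beat table CSV (`<name>_beats.csv`),
#' the cardiac panel JSON (`<name>_panel.json`) and a Poincare figure
#' (`<name>_poincare.pdf`). A combined one-row-per-fish summary CSV and a
#' plain-text run log (all parameters, flagged cycles, failures) land at the
#' top of `out_dir`. A failure in one input is logged and reported without
#' aborting the batch.
#'
#' @param inputs character vector of table paths, or a (optionally named)
#'   list of `landmark_track` objects.
#' @param out_dir output directory, created if needed.
#' @param fps,scale_um_per_px acquisition metadata for path inputs.
#' @param figures write Poincare PDFs (default TRUE).
#' @param ... analysis parameters forwarded to [heart_scan()].
#' @return Invisibly, a list with `fits` (per-input `heart_scan` or `NULL`),
#'   `summary` (the combined data frame), and `failures` (named character
#'   vector of error messages).
#' @export
run_analysis <- function(inputs, out_dir, fps = 30, scale_um_per_px = NULL,
                         figures = TRUE, ...) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.character(inputs)) {
    nms <- tools::file_path_sans_ext(basename(inputs))
    inputs <- as.list(inputs)
  } else {
    nms <- names(inputs)
    if (is.null(nms)) nms <- sprintf("track%02d", seq_along(inputs))
  }
  nms <- make.unique(nms)

  log_lines <- c(sprintf("zebraheart run: %d input(s)", length(inputs)),
                 sprintf("parameters: fps=%g%s", fps,
                         if (length(list(...))) paste0(", ", paste(names(list(...)),
                           vapply(list(...), format, ""), sep = "=", collapse = ", ")) else ""))
  fits <- vector("list", length(inputs))
  names(fits) <- nms
  failures <- character(0)
  rows <- list()

  for (i in seq_along(inputs)) {
    nm <- nms[i]
    res <- tryCatch({
      fit <- heart_scan(inputs[[i]], fps = fps, scale_um_per_px = scale_um_per_px, ...)
      utils::write.csv(as.data.frame(fit$axes),
                       file.path(out_dir, paste0(nm, "_axes.csv")), row.names = FALSE)
      utils::write.csv(as.data.frame(fit$beats),
                       file.path(out_dir, paste0(nm, "_beats.csv")), row.names = FALSE)
      panel_to_json(fit$panel, poincare = fit$hrv,
                    path = file.path(out_dir, paste0(nm, "_panel.json")))
      if (figures && !is.null(fit$hrv)) {
        grDevices::pdf(file.path(out_dir, paste0(nm, "_poincare.pdf")), width = 5, height = 5)
        plot(fit$hrv, main = paste("Poincare:", nm))
        grDevices::dev.off()
      }
      fit
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      log_lines <- c(log_lines, sprintf("FAIL %s: %s", nm, conditionMessage(res)))
    } else {
      fits[[nm]] <- res
      cf <- coef(res)
      rows[[nm]] <- data.frame(name = nm, t(cf), n_beats = res$panel$n_beats,
                               n_flagged = sum(res$beats$flagged))
      log_lines <- c(log_lines, sprintf("ok   %s: %d beats, HR %.1f bpm%s", nm,
                     res$panel$n_beats, res$panel$heart_rate,
                     if (any(res$beats$flagged))
                       sprintf(" [flagged cycles: %s]",
                               paste(res$beats$beat[res$beats$flagged], collapse = ","))
                     else ""))
    }
  }

  summary_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0))
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"), row.names = FALSE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(fits = fits, summary = summary_df, failures = failures))
}

#' Descriptive group summaries of cardiac panels
#'
#' Per group and parameter: n, mean and SD (mean +/- SD presentation). SD
#' for a single-member group is reported as `NA`, not zero — one fish gives
#' no dispersion estimate. Inferential statistics are intentionally out of
#' scope.
#'
#' @param groups a named list; each element a list of `cardiac_panel`
#'   objects (or `heart_scan` fits, whose panels and HRV are extracted).
#' @return A data frame with columns `group`, `parameter`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(groups) {
  if (!length(groups) || is.null(names(groups)) || any(names(groups) == ""))
    zh_parameter_error("groups must be a non-empty named list")
  pars <- c("heart_rate", "EDV", "ESV", "SV", "CO", "EF", "SF", "sd1", "sd2")
  out <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    if (!length(members))
      zh_parameter_error(sprintf("group '%s' is empty", g))
    vals <- vapply(members, function(m) {
      if (inherits(m, "heart_scan")) return(coef(m))
      if (inherits(m, "cardiac_panel"))
        return(c(heart_rate = m$heart_rate, EDV = m$EDV, ESV = m$ESV, SV = m$SV,
                 CO = m$CO, EF = m$EF, SF = m$SF, sd1 = NA_real_, sd2 = NA_real_))
      zh_parameter_error("group members must be cardiac_panel or heart_scan objects")
    }, numeric(length(pars)))
    for (p in pars) {
      v <- vals[p, ]
      out[[length(out) + 1L]] <- data.frame(
        group = g, parameter = p, n = sum(!is.na(v)),
        mean = mean(v, na.rm = TRUE),
        sd = if (sum(!is.na(v)) >= 2L) stats::sd(v, na.rm = TRUE) else NA_real_
      )
    }
  }
  do.call(rbind, out)
}
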