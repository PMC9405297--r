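#' Poincare-plot heart-rate-variability indices
#'
#' Scatters each inter-beat interval against the next and summarizes the
#' cloud by its dispersion across and along the identity line. With
#' d_n = IBI_n - IBI_{n+1} and s_n = IBI_n + IBI_{n+1}:
#' sd1 = sqrt(Var(d) / 2) measures instantaneous (beat-to-beat) variability,
#' sd2 = sqrt(Var(s) / 2) continuous long-term variability; variances use the
#' n-1 denominator for unbiasedness at small beat counts. For i.i.d.
#' intervals of SD sigma both indices estimate sigma; positive lag-1
#' autocorrelation pushes sd2 above sd1.
#'
#' The descriptive ellipse is centered at (mean IBI, mean IBI), aligned at
#' +/-45 degrees to the identity line, with semi-axes sd1 * c and sd2 * c
#' where c = sqrt(qchisq(confidence, df = 2)); it overlays the scatter and
#' plays no part in computing the indices.
#'
#' @param ibis inter-beat intervals in seconds (at least 3).
#' @param confidence coverage of the plotted ellipse (default 0.95).
#' @return A `poincare_result` list: `sd1`, `sd2` (seconds), `center`,
#'   `ellipse_semi_axes` (c(sd2, sd1) scaled, along and across the identity
#'   line), `confidence`, `pairs` (data frame `ibi_n`, `ibi_next`).
#' @export
poincare <- function(ibis, confidence = 0.95) {
  if (length(ibis) < 3L)
    zh_insufficient_beats("need at least 3 inter-beat intervals (2 Poincare pairs)")
  if (any(!is.finite(ibis)) || any(ibis <= 0))
    zh_domain_error("all inter-beat intervals must be finite and positive")
  if (confidence <= 0 || confidence >= 1)
    zh_parameter_error("confidence must be in (0, 1)")
  a <- ibis[-length(ibis)]
  b <- ibis[-1L]
  d <- a - b
  s <- a + b
  sd1 <- sqrt(stats::var(d) / 2)
  sd2 <- sqrt(stats::var(s) / 2)
  cc <- sqrt(stats::qchisq(confidence, df = 2))
  structure(list(
    sd1 = sd1, sd2 = sd2,
    center = c(mean(ibis), mean(ibis)),
    ellipse_semi_axes = c(along = sd2 * cc, across = sd1 * cc),
    confidence = confidence,
    pairs = data.frame(ibi_n = a, ibi_next = b)
  ), class = "poincare_result")
}

#' @export
print.poincare_result <- function(x, ...) {
  cat(sprintf("<poincare_result> %d pairs, mean IBI %.3f s\n", nrow(x$pairs), x$center[1]))
  cat(sprintf("  sd1 = %.4f s (instantaneous)\n  sd2 = %.4f s (long-term)\n", x$sd1, x$sd2))
  cat(sprintf("  %.0f%% ellipse semi-axes: %.4f (along identity), %.4f (across)\n",
              100 * x$confidence, x$ellipse_semi_axes["along"], x$ellipse_semi_axes["across"]))
  invisible(x)
}

#' Plot a Poincare scatter with its confidence ellipse
#'
#' @param x a `poincare_result`.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.poincare_result <- function(x, main = "Poincare plot", ...) {
  p <- x$pairs
  lim <- range(p$ibi_n, p$ibi_next)
  pad <- 0.1 * diff(lim)
  lim <- lim + c(-pad, pad)
  graphics::plot(p$ibi_n, p$ibi_next, xlim = lim, ylim = lim, asp = 1,
                 xlab = expression(IBI[n] ~ "(s)"), ylab = expression(IBI[n + 1] ~ "(s)"),
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.6),
                 main = main, ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  th <- seq(0, 2 * pi, length.out = 181)
  u <- x$ellipse_semi_axes["along"] * cos(th)
  v <- x$ellipse_semi_axes["across"] * sin(th)
  r <- sqrt(2) / 2  # rotate +45 degrees onto the identity line
  graphics::lines(x$center[1] + r * (u - v), x$center[2] + r * (u + v),
                  col = "firebrick", lwd = 2)
  graphics::points(x$center[1], x$center[2], pch = 3, col = "firebrick")
  invisible(x)
}
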