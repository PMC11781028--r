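#' Quick-look plot of a probability series
#'
#' Scatter of per-minute reactant-detection probability with the fitted
#' initial-velocity line overlaid when supplied. Decoration only; nothing
#' here is load-bearing for the analysis.
#'
#' @param series A [probability_series()] result.
#' @param fit Optional `kinetic_fit` to overlay.
#' @param ... Passed to [plot()].
#' @return Invisibly, `series`.
#' @export
plot_probability_series <- function(series, fit = NULL, ...) {
  plot(series$minute, series$probability_pct,
       xlab = "time (min)", ylab = "P(reactant) [%]",
       ylim = c(0, 100), pch = 19, ...)
  if (!is.null(fit)) {
    graphics::abline(fit$intercept, fit$slope, lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("m = %.2f %%/min, R2 = %.2f",
                                      fit$slope, fit$r_squared))
  }
  invisible(series)
}

#' Stacked per-minute amplitude PDFs (ridgeline-style)
#'
#' @param events Event data.frame.
#' @param minutes Which minutes to draw, default `c(1, 10, 20, 30)`.
#' @param ... Passed to [estimate_pdf()].
#' @return Invisibly, the list of PDFs drawn.
#' @export
plot_amplitude_pdfs <- function(events, minutes = c(1, 10, 20, 30), ...) {
  bins <- bin_by_minute(events, n_minutes = max(minutes))
  grid <- amplitude_grid(events$amp_nA)
  pdfs <- lapply(bins[minutes], estimate_pdf, grid = grid, ...)
  keep <- !vapply(pdfs, is.null, TRUE)
  pdfs <- pdfs[keep]; minutes <- minutes[keep]
  if (!length(pdfs)) .fail("no usable minutes to plot")
  dmax <- max(vapply(pdfs, function(p) max(p$density), 0))
  plot(NA, xlim = range(grid), ylim = c(0, length(pdfs) * dmax * 0.8 + dmax),
       xlab = "peak amplitude (nA)", ylab = "", yaxt = "n")
  for (i in seq_along(pdfs)) {
    off <- (length(pdfs) - i) * dmax * 0.8
    graphics::lines(grid, pdfs[[i]]$density + off)
    graphics::text(grid[1], off + dmax * 0.3, paste0(minutes[i], " min"),
                   adj = 0, cex = 0.8)
  }
  invisible(pdfs)
}
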