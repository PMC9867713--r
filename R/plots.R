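# Base-graphics summaries of the package's two signature plots.

#' Plot a positivity-versus-distance profile with its fitted slope
#'
#' @param profile data.frame from [binPositiveFractions()].
#' @param fit optional one-row data.frame from [fitDistanceSlope()];
#'   drawn as a line with the slope annotated as \emph{m}.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotDistanceProfile <- function(profile, fit = NULL, ...) {
  x <- profile$bin_index
  y <- profile$fraction_percent
  graphics::plot(x, y, type = "b", pch = 16, xaxt = "n",
                 xlab = "distance from disrupted areas",
                 ylab = "positive cells (%)",
                 ylim = c(0, max(100, y, na.rm = TRUE)), ...)
  graphics::axis(1, at = x, labels = profile$bin)
  if (!is.null(fit)) {
    graphics::abline(fit$intercept, fit$m, lty = 2)
    graphics::legend("topright", bty = "n",
                     legend = sprintf("m = %.4f (r2 = %.2f)", fit$m,
                                      fit$r_squared))
  }
  invisible(NULL)
}

#' Plot aggregated radial profiles with quartile bands
#'
#' Mean radial profile per condition with a shaded band between the 1st
#' and 3rd quartiles of the individual colony profiles, after control-
#' maximum normalization ([aggregateProfiles()]).
#'
#' @param agg data.frame from [aggregateProfiles()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plotProfileAggregate <- function(agg, ...) {
  conds <- unique(agg$condition)
  cols <- grDevices::hcl.colors(max(2L, length(conds)), "Dark 2")
  graphics::plot(NA, xlim = range(agg$r_um), ylim = c(0, max(agg$q3) * 1.05),
                 xlab = "radius (um)", ylab = "normalized intensity", ...)
  for (k in seq_along(conds)) {
    d <- agg[agg$condition == conds[k], ]
    band <- grDevices::adjustcolor(cols[k], alpha.f = 0.25)
    graphics::polygon(c(d$r_um, rev(d$r_um)), c(d$q1, rev(d$q3)),
                      col = band, border = NA)
    graphics::lines(d$r_um, d$mean, col = cols[k], lwd = 2)
  }
  graphics::legend("topleft", legend = conds, col = cols[seq_along(conds)],
                   lwd = 2, bty = "n")
  invisible(NULL)
}
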