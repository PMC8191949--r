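## Figures: per-cell tracings with the average curve, and the two-group
## nucleus-intensity histogram.

#' Plot per-cell axial tracings with their average
#'
#' Draws every normalized per-cell profile as a thin line over position
#' (fraction of cell length, initial measured end at 0) with the
#' positionwise mean overlaid, the standard way per-condition
#' localization tracings are presented.
#'
#' @param profiles list of normalized [AxialProfile]s.
#' @param ensemble optional precomputed [ProfileEnsemble]; computed from
#'   `profiles` when `NULL`.
#' @param col tracing color.
#' @param main plot title.
#' @return invisibly, the ensemble used.
#' @export
plotProfiles <- function(profiles, ensemble = NULL,
                         col = grDevices::adjustcolor("grey40", 0.35),
                         main = "Axial reporter profiles") {
  if (is.null(ensemble)) ensemble <- averageProfiles(profiles)
  ymax <- max(vapply(profiles, function(p) max(p@valuesNorm), numeric(1)))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, max(ymax, 1.2)),
                 xlab = "Position along cell (fraction of length)",
                 ylab = "Normalized intensity (end = 1)", main = main)
  for (p in profiles) {
    graphics::lines(p@positions, p@valuesNorm, col = col, lwd = 0.6)
  }
  graphics::lines(ensemble@positions, ensemble@mean, lwd = 2.5)
  graphics::abline(h = 1, lty = 3)
  invisible(ensemble)
}

#' Plot the average tracings of several conditions
#'
#' @param ensembles named list of [ProfileEnsemble]s.
#' @param cols line colors, recycled.
#' @param main plot title.
#' @export
plotEnsembles <- function(ensembles, cols = grDevices::palette(),
                          main = "Average axial profiles") {
  ymax <- max(vapply(ensembles, function(e) max(e@mean), numeric(1)))
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, max(ymax, 1.2)),
                 xlab = "Position along cell (fraction of length)",
                 ylab = "Normalized intensity (end = 1)", main = main)
  cols <- rep_len(cols, length(ensembles))
  for (i in seq_along(ensembles)) {
    graphics::lines(ensembles[[i]]@positions, ensembles[[i]]@mean,
                    col = cols[i], lwd = 2)
  }
  graphics::abline(h = 1, lty = 3)
  graphics::legend("topleft", legend = names(ensembles), col = cols,
                   lwd = 2, bty = "n")
}

#' Histogram of per-cell nucleus intensities for two groups
#'
#' Mirrors the usual presentation of a two-group DNA-stain intensity
#' comparison: shared bins, side-by-side bars, group means in the legend.
#'
#' @param comparison a [GroupComparison] from [compareGroups()].
#' @param cols two bar colors.
#' @param main plot title.
#' @export
plotDapiHistogram <- function(comparison,
                              cols = c("#1f78b4", "#33a02c"),
                              main = "Nucleus DAPI intensity") {
  mids <- (utils::head(comparison@breaks, -1) +
             utils::tail(comparison@breaks, -1)) / 2
  graphics::barplot(t(comparison@counts), beside = TRUE,
                    names.arg = signif(mids, 3), las = 2,
                    col = cols, border = NA,
                    xlab = "Mean in-mask DAPI intensity (counts)",
                    ylab = "Cells", main = main)
  graphics::legend("topright", bty = "n", fill = cols, legend = sprintf(
    "%s (n=%d, mean %.0f)", comparison@labels, comparison@n,
    comparison@means))
}
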