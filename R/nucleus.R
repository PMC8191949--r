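## DAPI nucleus quantification: Otsu mask of the phage nucleoid within a
## cropped cell ROI, raw in-mask mean, complementary-mask background, and
## two-group comparison with a shared histogram.

#' Quantify the phage nucleus from the DNA channel of one cell
#'
#' Crops to the cell ROI, Otsu-thresholds the in-ROI DAPI pixels
#' ([otsuThreshold()]), takes the largest connected above-threshold
#' component as the nucleus mask, and reports the mean raw DAPI intensity
#' inside the mask together with the mean over the in-ROI complement of
#' the mask as the background estimate. Means are taken on the raw image
#' — no background subtraction is applied (adding a constant to the image
#' shifts both statistics by exactly that constant); the subtracted
#' variant is available via [meanMinusBackground()].
#'
#' @param dapi DNA-channel image matrix.
#' @param roi a [CellROI], normally one flagged infected.
#' @return a [NucleusQuant].
#' @export
quantifyNucleus <- function(dapi, roi) {
  box <- roiBox(roi)
  local <- dapi[box$rows, box$cols]
  ot <- otsuThreshold(local[box$mask]) # degenerate DAPI errors out here
  bright <- box$mask & local > threshold(ot)
  if (!any(bright)) {
    stopWith("maskError", sprintf(
      "cell %d: no in-ROI pixels above the Otsu threshold", roi@cellId))
  }
  blob <- largestComponent(bright)
  comp <- box$mask & !blob
  if (!any(comp)) {
    stopWith("maskError", sprintf(
      "cell %d: nucleus mask covers the whole ROI", roi@cellId))
  }
  rcLocal <- indexToRc(which(blob), dim(blob))
  globalIdx <- rcToIndex(
    cbind(rcLocal[, 1L] + box$r0, rcLocal[, 2L] + box$c0), roi@imageDim)
  new("NucleusQuant",
      cellId = roi@cellId,
      nucleusPixels = as.integer(sort(globalIdx)),
      imageDim = roi@imageDim,
      meanDapi = mean(local[blob]),
      background = mean(local[comp]),
      maskArea = as.integer(sum(blob)))
}

#' Compare per-cell nucleus intensities between two groups
#'
#' Builds a shared equal-width histogram over the pooled range of the
#' per-cell mean nucleus intensities of two groups and reports per-group
#' mean, standard deviation and n, plus the percent difference of group
#' means relative to the first (reference) group:
#' `100 * (meanA - meanB) / meanA`.
#'
#' @param groupA,groupB lists of [NucleusQuant] (or numeric vectors of
#'   per-cell mean intensities); `groupA` is the reference.
#' @param nBins number of shared histogram bins.
#' @param labels group labels, reference first.
#' @return a [GroupComparison].
#' @examples
#' compareGroups(rep(7500, 5), rep(6000, 5))
#' @export
compareGroups <- function(groupA, groupB, nBins = 20L,
                          labels = c("A", "B")) {
  asValues <- function(g) {
    if (is.numeric(g)) return(as.numeric(g))
    vapply(g, function(q) q@meanDapi, numeric(1))
  }
  a <- asValues(groupA)
  b <- asValues(groupB)
  if (length(a) == 0L || length(b) == 0L) {
    stopWith("emptyPopulationError", "both groups must be non-empty")
  }
  pooled <- range(c(a, b))
  if (pooled[1L] == pooled[2L]) pooled <- pooled + c(-0.5, 0.5)
  breaks <- seq(pooled[1L], pooled[2L], length.out = nBins + 1L)
  countsOf <- function(v) {
    bin <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L),
                nBins)
    tabulate(bin, nbins = nBins)
  }
  meanA <- mean(a)
  meanB <- mean(b)
  new("GroupComparison",
      labels = labels,
      n = c(length(a), length(b)),
      means = c(meanA, meanB),
      sds = c(if (length(a) > 1) stats::sd(a) else 0,
              if (length(b) > 1) stats::sd(b) else 0),
      percentDifference = 100 * (meanA - meanB) / meanA,
      breaks = breaks,
      counts = cbind(countsOf(a), countsOf(b)))
}
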