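## Cell detection and per-cell geometry: Otsu thresholding, connected
## component segmentation, principal-axis estimation, and the
## "bright, circular, central DAPI focus" infection criterion.

#' Otsu's threshold by exhaustively maximizing between-class variance
#'
#' Bins the pixel values into `nBins` equal-width bins over
#' `[min, max]` and returns the threshold `t*` maximizing the
#' between-class variance `sigma_b^2(t) = w0 w1 (mu0 - mu1)^2`, where
#' class 0 comprises bins `<= t` (bin midpoints are used as class
#' intensities). Ties are broken deterministically as the floor of the
#' mean index of the argmax set; the threshold is reported in intensity
#' units as the upper edge of the selected bin.
#'
#' @param pixels numeric vector (or matrix) of intensities.
#' @param nBins number of histogram bins.
#' @return an [OtsuResult].
#' @examples
#' threshold(otsuThreshold(c(rep(0, 50), rep(255, 50))))
#' @export
otsuThreshold <- function(pixels, nBins = 256L) {
  px <- as.numeric(pixels)
  px <- px[is.finite(px)]
  if (length(px) < 2L || max(px) == min(px)) {
    stopWith("degenerateHistogramError",
             "cannot threshold a constant (or empty) image")
  }
  lo <- min(px)
  hi <- max(px)
  binWidth <- (hi - lo) / nBins
  bin <- pmin(floor((px - lo) / binWidth) + 1L, nBins)
  counts <- tabulate(bin, nbins = nBins)
  mids <- lo + (seq_len(nBins) - 0.5) * binWidth

  p <- counts / sum(counts)
  w0 <- cumsum(p)
  m <- cumsum(p * mids)
  mTot <- m[nBins]
  ## sigma_b^2 for every candidate t = 1 .. nBins-1 (class 0 = bins <= t)
  t <- seq_len(nBins - 1L)
  w0t <- w0[t]
  w1t <- 1 - w0t
  sigmaB <- numeric(nBins - 1L)
  ok <- w0t > 0 & w1t > 0
  mu0 <- m[t][ok] / w0t[ok]
  mu1 <- (mTot - m[t][ok]) / w1t[ok]
  sigmaB[ok] <- w0t[ok] * w1t[ok] * (mu0 - mu1)^2
  best <- max(sigmaB)
  tStar <- floor(mean(which(sigmaB == best)))
  new("OtsuResult",
      threshold = lo + tStar * binWidth,
      betweenClassVariance = best,
      histogram = as.numeric(counts),
      breaks = lo + (0:nBins) * binWidth)
}

#' Segment cells in a micrograph
#'
#' Detects cell footprints by global Otsu thresholding of a smoothed
#' composite (the sum of the selected channels), followed by hole
#' filling, 8-connected component labeling, and discarding of components
#' outside `[minArea, maxArea]` or touching the image border (a cell must
#' be fully in-bounds by at least one pixel). The bright phage nucleus
#' makes the composite histogram trimodal (background / cytoplasm /
#' nucleus), and a single global Otsu threshold can land between
#' cytoplasm and nucleus instead of between background and cell; the
#' threshold is therefore refined by a second Otsu pass on the lower
#' class, adopted whenever it explains a comparable share of the
#' between-class variance (a two-level Otsu with model selection). Holes
#' (e.g. a dim nucleus interior in nucleus-excluded cells) are filled.
#' Cell ids are assigned in raster order of the component centroids.
#'
#' @param images a [SceneRender], a named list of channel matrices, or a
#'   single matrix.
#' @param minArea,maxArea component area bounds, px^2.
#' @param smoothSigma Gaussian smoothing sigma (px) applied before
#'   thresholding.
#' @param channels channels summed into the composite when `images` has
#'   named channels; ignored otherwise.
#' @param subSplitRatio adopt the second-pass threshold when its
#'   between-class variance is at least this fraction of the first
#'   pass's.
#' @return list of [CellROI] (axis and infection flag unset).
#' @examples
#' sp <- SceneSpec(imageShape = c(120, 120),
#'                 cells = list(CellSpec(center = c(60, 60))), seed = 1)
#' length(segmentCells(renderScene(sp)))
#' @export
segmentCells <- function(images, minArea = 100, maxArea = 5000,
                         smoothSigma = 1,
                         channels = c("gfp", "dapi", "membrane"),
                         subSplitRatio = 0.25) {
  chans <- if (is(images, "SceneRender")) {
    sceneImages(images)
  } else if (is.matrix(images)) {
    list(images)
  } else {
    images
  }
  if (!is.null(names(chans)) && all(channels %in% names(chans))) {
    chans <- chans[channels]
  }
  composite <- Reduce(`+`, lapply(chans, function(m) m * 1.0))
  sm <- safeGblur(composite, smoothSigma)
  ot <- tryCatch(
    otsuThreshold(sm),
    degenerateHistogramError = function(e) {
      stopWith("noCellsError", "image is constant; no cells found")
    }
  )
  thr <- threshold(ot)
  below <- sm[sm <= thr]
  if (length(below) > 1L && max(below) > min(below)) {
    ot0 <- otsuThreshold(below)
    if (ot0@betweenClassVariance >= subSplitRatio * ot@betweenClassVariance) {
      thr <- threshold(ot0)
    }
  }
  bw <- sm > thr
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(bw), ncol(bw))
  nComp <- max(lab)
  if (nComp == 0L) stopWith("noCellsError", "no above-threshold components")

  keep <- list()
  for (i in seq_len(nComp)) {
    idx <- which(lab == i)
    area <- length(idx)
    if (area < minArea || area > maxArea) next
    rc <- indexToRc(idx, dim(lab))
    if (min(rc[, 1L]) <= 0L || min(rc[, 2L]) <= 0L ||
        max(rc[, 1L]) >= nrow(lab) - 1L || max(rc[, 2L]) >= ncol(lab) - 1L) {
      message(sprintf("segmentCells: discarding border-touching component %d", i))
      next
    }
    keep[[length(keep) + 1L]] <-
      list(idx = idx, centroid = c(mean(rc[, 1L]), mean(rc[, 2L])))
  }
  if (length(keep) == 0L) {
    stopWith("noCellsError", "no components survive the area/border filters")
  }
  ord <- order(vapply(keep, function(k) k$centroid[1L], numeric(1)),
               vapply(keep, function(k) k$centroid[2L], numeric(1)))
  lapply(seq_along(ord), function(newId) {
    cellROI(newId, keep[[ord[newId]]]$idx, dim(lab))
  })
}

#' Build ROIs from a pre-drawn label image
#'
#' Escape hatch for externally provided cell masks (for example ROIs
#' drawn by hand and exported as a label image): pixels with value `k > 0`
#' become the mask of cell `k`.
#'
#' @param label integer matrix (or path to a label TIFF readable by
#'   [readLabelTiff()]).
#' @return list of [CellROI].
#' @export
roisFromLabels <- function(label) {
  if (is.character(label)) label <- readLabelTiff(label)
  ids <- setdiff(sort(unique(as.integer(label))), 0L)
  if (length(ids) == 0L) stopWith("noCellsError", "label image is empty")
  lapply(seq_along(ids), function(k) {
    cellROI(k, which(label == ids[k]), dim(label))
  })
}

#' Establish the long axis of a cell
#'
#' The axis direction is the principal eigenvector of the mask's second
#' central moment matrix; the endpoints are the extreme projections of
#' mask pixels onto the line through the centroid along that direction.
#' `axisP0` — the "initial measured end" — is fixed deterministically as
#' the lexicographically smaller endpoint (row, then col). Nearly
#' isotropic masks (eigenvalue ratio below `minElongation`) have no
#' meaningful long axis and raise an `axisAmbiguousError`.
#'
#' @param roi a [CellROI].
#' @param minElongation minimum major/minor eigenvalue ratio.
#' @return the [CellROI] with `axisP0`, `axisP1` and `lengthPx` set.
#' @examples
#' m <- matrix(FALSE, 30, 60); m[10:19, 5:44] <- TRUE
#' longAxis(cellROI(1, m))
#' @export
longAxis <- function(roi, minElongation = 1.05) {
  rc <- indexToRc(roi@pixels, roi@imageDim)
  if (nrow(rc) < 4L) {
    stopWith("axisAmbiguousError", "mask too small for axis estimation")
  }
  centered <- sweep(rc, 2L, colMeans(rc))
  covMat <- crossprod(centered) / nrow(rc)
  eig <- eigen(covMat, symmetric = TRUE)
  if (eig$values[2L] <= 0 || eig$values[1L] / eig$values[2L] >= minElongation) {
    u <- eig$vectors[, 1L]
  } else {
    stopWith("axisAmbiguousError", sprintf(
      "cell %d mask is nearly isotropic (eigenvalue ratio %.3f)",
      roi@cellId, eig$values[1L] / eig$values[2L]))
  }
  proj <- centered %*% u
  centroid <- colMeans(rc)
  pA <- centroid + u * min(proj)
  pB <- centroid + u * max(proj)
  ends <- if (pA[1L] < pB[1L] || (pA[1L] == pB[1L] && pA[2L] <= pB[2L])) {
    list(pA, pB)
  } else {
    list(pB, pA)
  }
  roi@axisP0 <- as.numeric(ends[[1L]])
  roi@axisP1 <- as.numeric(ends[[2L]])
  roi@lengthPx <- sqrt(sum((roi@axisP1 - roi@axisP0)^2))
  roi
}

#' Flag a cell as phage-infected from its DNA channel
#'
#' Implements the operational version of "infected cells were identified
#' by the presence of a bright, circular DAPI stain in the center of the
#' cell": within the ROI, DAPI pixels are Otsu-thresholded and the
#' largest bright component is taken; the cell is flagged infected iff
#' (a) the component's mean intensity is at least `brightnessMin` times
#' the mean of the in-ROI complement, (b) its circularity
#' `4 pi area / perimeter^2` (chain-code perimeter, so a digital disk
#' scores close to 1) is at least `circularityMin`, and (c) its centroid
#' projects into the central `centerBand` fraction of the cell's long
#' axis. Any failed criterion (including a degenerate in-ROI histogram)
#' yields `infected = FALSE` rather than an error. The defaults put the
#' operating point midway between the two blob populations seen in
#' synthetic infected vs uninfected cells: a central DAPI focus scores
#' circularity near 1 with focus/complement contrast well above 1.9,
#' while the brightest blob of an uninfected cell is the elongated host
#' nucleoid (circularity below ~0.75, contrast below ~1.8).
#'
#' @param roi a [CellROI] with its axis set (see [longAxis()]).
#' @param dapi DNA-channel image matrix.
#' @param circularityMin minimum circularity of the bright focus.
#' @param brightnessMin minimum focus/complement mean-intensity ratio.
#' @param centerBand width of the central axial acceptance band as a
#'   fraction of cell length (default: the central third).
#' @return the [CellROI] with `infected` set.
#' @export
flagInfected <- function(roi, dapi, circularityMin = 0.8,
                         brightnessMin = 1.5, centerBand = 1 / 3) {
  if (anyNA(roi@axisP0)) {
    stopWith("axisAmbiguousError",
             "flagInfected requires a CellROI with its long axis set")
  }
  roi@infected <- FALSE
  box <- roiBox(roi)
  local <- dapi[box$rows, box$cols]
  ot <- tryCatch(otsuThreshold(local[box$mask]),
                 degenerateHistogramError = function(e) NULL)
  if (is.null(ot)) return(roi)
  bright <- box$mask & local > threshold(ot)
  if (!any(bright)) return(roi)
  blob <- largestComponent(bright)
  comp <- box$mask & !blob
  if (!any(comp)) return(roi)
  if (mean(local[blob]) < brightnessMin * mean(local[comp])) return(roi)
  shape <- maskShape(blob)
  if (is.na(shape$circularity) || shape$circularity < circularityMin) {
    return(roi)
  }
  rc <- indexToRc(which(blob), dim(blob))
  blobCentroid <- c(mean(rc[, 1L]) + box$r0, mean(rc[, 2L]) + box$c0)
  u <- (roi@axisP1 - roi@axisP0) / roi@lengthPx
  s <- sum((blobCentroid - roi@axisP0) * u) / roi@lengthPx
  if (abs(s - 0.5) > centerBand / 2) return(roi)
  roi@infected <- TRUE
  roi
}
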