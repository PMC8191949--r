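#' @import methods
NULL

PHENOTYPES <- c("imported", "excluded", "uniform")
CALLS <- c("imported", "excluded", "mixed_ambiguous")
CHANNELS <- c("gfp", "dapi", "membrane")

## ---------------------------------------------------------------------------
## OpticsModel
## ---------------------------------------------------------------------------

#' Optical and camera model for synthetic micrographs
#'
#' Describes the imaging system emulated by [renderScene()]: sampling
#' (nm per pixel), an isotropic Gaussian point-spread function, and an
#' sCMOS/CCD-style camera with Poisson shot noise, a constant offset and
#' Gaussian read noise.
#'
#' @slot pixelSize physical size of one pixel, nm (default 65, typical of
#'   a 100x widefield system).
#' @slot psfSigma standard deviation of the Gaussian PSF, nm (default 130,
#'   i.e. two pixels at the default sampling).
#' @slot cameraOffset constant camera offset added to every pixel, counts.
#' @slot readNoiseSd standard deviation of Gaussian read noise, counts.
#' @slot photonScale expected counts per unit emitter density.
#'
#' @param pixelSize,psfSigma,cameraOffset,readNoiseSd,photonScale see slots.
#' @return `OpticsModel()` returns an OpticsModel object.
#' @examples
#' OpticsModel(psfSigma = 0, readNoiseSd = 0)
#' @export OpticsModel
#' @exportClass OpticsModel
OpticsModel <- setClass(
  "OpticsModel",
  slots = c(
    pixelSize = "numeric",
    psfSigma = "numeric",
    cameraOffset = "numeric",
    readNoiseSd = "numeric",
    photonScale = "numeric"
  ),
  prototype = list(
    pixelSize = 65,
    psfSigma = 130,
    cameraOffset = 100,
    readNoiseSd = 2,
    photonScale = 1
  )
)

setValidity("OpticsModel", function(object) {
  msg <- character(0)
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
  if (object@photonScale <= 0) msg <- c(msg, "photonScale must be > 0")
  if (object@cameraOffset < 0) msg <- c(msg, "cameraOffset must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## CellSpec
## ---------------------------------------------------------------------------

#' Specification of one synthetic cell
#'
#' A rod-shaped cell is modelled as a 2-D spherocylinder (rectangle capped
#' by two semicircles). An infected cell additionally carries a circular
#' phage-nucleus disk on its long axis; in the DNA channel the disk is
#' bright (the "bright, circular DAPI stain" used to identify infected
#' cells) and in the reporter channel its emitter density is
#' `gfpContrast` times the cytoplasmic density. An uninfected cell has no
#' nucleus disk in any channel.
#'
#' @slot center (row, col) position of the cell center, 0-based pixels.
#' @slot length,width cell length and width, micrometres; `length >= width`.
#' @slot orientation long-axis angle, radians (0 = along image columns).
#' @slot infected logical; whether the cell carries a phage nucleus.
#' @slot nucleusRadiusFrac nucleus disk radius as a fraction of `width / 2`.
#' @slot nucleusAxialPos nucleus center position along the axis as a
#'   fraction of cell length in `[0, 1]`; 0.5 = midcell.
#' @slot phenotype one of `"imported"`, `"excluded"`, `"uniform"`.
#' @slot gfpContrast ratio of in-nucleus to cytoplasmic reporter emitter
#'   density (> 1 imported, < 1 excluded, 1 uniform).
#' @slot gfpCytoplasmLevel cytoplasmic reporter emitter density (counts at
#'   unit photon scale).
#' @slot dapiNucleusLevel DNA-stain emitter density inside the nucleus disk.
#' @slot dapiBackgroundLevel DNA-stain emitter density in the cytoplasm
#'   (host nucleoid background).
#' @slot membraneLevel membrane-stain emitter density on the cell outline.
#'
#' @param center,length,width,orientation,infected,nucleusRadiusFrac,nucleusAxialPos,phenotype,gfpContrast,gfpCytoplasmLevel,dapiNucleusLevel,dapiBackgroundLevel,membraneLevel
#'   see slots.
#' @return `CellSpec()` returns a CellSpec object.
#' @examples
#' CellSpec(center = c(50, 50), phenotype = "excluded", gfpContrast = 0.2)
#' @export CellSpec
#' @exportClass CellSpec
CellSpec <- setClass(
  "CellSpec",
  slots = c(
    center = "numeric",
    length = "numeric",
    width = "numeric",
    orientation = "numeric",
    infected = "logical",
    nucleusRadiusFrac = "numeric",
    nucleusAxialPos = "numeric",
    phenotype = "character",
    gfpContrast = "numeric",
    gfpCytoplasmLevel = "numeric",
    dapiNucleusLevel = "numeric",
    dapiBackgroundLevel = "numeric",
    membraneLevel = "numeric"
  ),
  prototype = list(
    center = c(50, 50),
    length = 3,
    width = 1,
    orientation = 0,
    infected = TRUE,
    nucleusRadiusFrac = 0.8,
    nucleusAxialPos = 0.5,
    phenotype = "uniform",
    gfpContrast = 1,
    gfpCytoplasmLevel = 1500,
    dapiNucleusLevel = 7500,
    dapiBackgroundLevel = 800,
    membraneLevel = 3000
  )
)

setValidity("CellSpec", function(object) {
  msg <- character(0)
  if (length(object@center) != 2L) msg <- c(msg, "center must be (row, col)")
  if (object@length < object@width) {
    msg <- c(msg, "length must be >= width (rod geometry)")
  }
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (!(object@nucleusRadiusFrac > 0 && object@nucleusRadiusFrac <= 1)) {
    msg <- c(msg, "nucleusRadiusFrac must be in (0, 1]")
  }
  if (object@nucleusAxialPos < 0 || object@nucleusAxialPos > 1) {
    msg <- c(msg, "nucleusAxialPos must be in [0, 1]")
  }
  if (!object@phenotype %in% PHENOTYPES) {
    msg <- c(msg, sprintf("phenotype must be one of %s",
                          paste(PHENOTYPES, collapse = ", ")))
  }
  if (object@gfpContrast < 0) msg <- c(msg, "gfpContrast must be >= 0")
  if (object@phenotype == "imported" && object@gfpContrast < 1) {
    msg <- c(msg, "imported phenotype requires gfpContrast >= 1")
  }
  if (object@phenotype == "excluded" && object@gfpContrast > 1) {
    msg <- c(msg, "excluded phenotype requires gfpContrast <= 1")
  }
  if (object@phenotype == "uniform" && object@gfpContrast != 1) {
    msg <- c(msg, "uniform phenotype requires gfpContrast == 1")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SceneSpec
## ---------------------------------------------------------------------------

#' Specification of one synthetic field of view
#'
#' Fully parametrizes one multi-channel synthetic micrograph: image shape,
#' the cells it contains, the optics/camera model and the RNG seed.
#' Rendering the same SceneSpec (including seed) twice yields bit-identical
#' images.
#'
#' @slot imageShape (rows, cols) of the rendered image.
#' @slot cells list of [CellSpec] objects; footprints must not overlap.
#' @slot optics an [OpticsModel].
#' @slot seed integer RNG seed used for the noise draws.
#'
#' @param imageShape,cells,optics,seed see slots.
#' @return `SceneSpec()` returns a SceneSpec object.
#' @examples
#' SceneSpec(imageShape = c(120, 120),
#'           cells = list(CellSpec(center = c(60, 60))), seed = 1)
#' @export SceneSpec
#' @exportClass SceneSpec
SceneSpec <- setClass(
  "SceneSpec",
  slots = c(
    imageShape = "integer",
    cells = "list",
    optics = "OpticsModel",
    seed = "integer"
  ),
  prototype = list(
    imageShape = c(256L, 256L),
    cells = list(),
    optics = OpticsModel(),
    seed = 1L
  )
)

SceneSpec <- function(imageShape = c(256L, 256L), cells = list(),
                      optics = OpticsModel(), seed = 1L) {
  new("SceneSpec", imageShape = as.integer(imageShape), cells = cells,
      optics = optics, seed = as.integer(seed))
}

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L)) {
    msg <- c(msg, "imageShape must be two integers >= 8")
  }
  if (!all(vapply(object@cells, is, logical(1), "CellSpec"))) {
    msg <- c(msg, "cells must be a list of CellSpec objects")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SceneRender
## ---------------------------------------------------------------------------

#' A rendered synthetic scene with its ground truth
#'
#' Returned by [renderScene()]. Holds one count matrix per channel (fixed
#' order: gfp, dapi, membrane) together with per-cell pixel-level ground
#' truth (cell mask, nucleus mask, tip-to-tip axis endpoints, phenotype,
#' true mean emitter densities) and a label matrix in which every cell
#' pixel belongs to exactly one cell.
#'
#' @slot images named list of matrices (`gfp`, `dapi`, `membrane`).
#' @slot groundTruth list with elements `cells` (per-cell list) and
#'   `label` (integer matrix of cell ids).
#' @slot spec the [SceneSpec] that produced the render.
#' @slot noise logical; whether camera noise was applied.
#' @exportClass SceneRender
setClass(
  "SceneRender",
  slots = c(
    images = "list",
    groundTruth = "list",
    spec = "SceneSpec",
    noise = "logical"
  )
)

#' @describeIn SceneRender-class channel images as a named list of matrices.
#' @param object,x a SceneRender.
#' @export
sceneImages <- function(x) x@images

#' @describeIn SceneRender-class ground-truth list (`cells`, `label`).
#' @export
groundTruth <- function(x) x@groundTruth

## ---------------------------------------------------------------------------
## CellROI
## ---------------------------------------------------------------------------

#' A detected (or declared) cell region of interest
#'
#' One cell as used by the measurement stages: its pixel mask, long-axis
#' endpoints, length, and infection status. Coordinates are 0-based
#' (row, col) with pixel-center semantics; `axisP0` is the "initial
#' measured end", fixed deterministically as the lexicographically smaller
#' endpoint (row, then col).
#'
#' @slot cellId integer id (raster order of centroids at segmentation).
#' @slot pixels 1-based linear indices (column-major) of mask pixels.
#' @slot imageDim (rows, cols) of the parent image.
#' @slot centroid (row, col) mask centroid, 0-based pixels.
#' @slot axisP0,axisP1 subpixel long-axis endpoints, 0-based (row, col);
#'   `NA` until [longAxis()] has been applied.
#' @slot lengthPx Euclidean distance between the axis endpoints.
#' @slot infected logical; `NA` until [flagInfected()] has been applied.
#' @exportClass CellROI
setClass(
  "CellROI",
  slots = c(
    cellId = "integer",
    pixels = "integer",
    imageDim = "integer",
    centroid = "numeric",
    axisP0 = "numeric",
    axisP1 = "numeric",
    lengthPx = "numeric",
    infected = "logical"
  ),
  prototype = list(
    axisP0 = c(NA_real_, NA_real_),
    axisP1 = c(NA_real_, NA_real_),
    lengthPx = NA_real_,
    infected = NA
  )
)

setValidity("CellROI", function(object) {
  msg <- character(0)
  if (length(object@pixels) == 0L) msg <- c(msg, "mask must be non-empty")
  if (length(object@imageDim) != 2L) msg <- c(msg, "imageDim must be length 2")
  npix <- prod(object@imageDim)
  if (any(object@pixels < 1L | object@pixels > npix)) {
    msg <- c(msg, "mask pixels outside image")
  }
  if (!is.na(object@lengthPx) && object@lengthPx <= 0) {
    msg <- c(msg, "lengthPx must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CellROI from a pixel mask
#'
#' @param cellId integer id.
#' @param pixels 1-based linear (column-major) indices of the mask, or a
#'   logical matrix.
#' @param imageDim (rows, cols); taken from the matrix if `pixels` is one.
#' @return a [CellROI] with centroid filled in and axis unset.
#' @examples
#' m <- matrix(FALSE, 20, 30); m[8:12, 5:25] <- TRUE
#' cellROI(1, m)
#' @export
cellROI <- function(cellId, pixels, imageDim = NULL) {
  if (is.matrix(pixels)) {
    imageDim <- dim(pixels)
    pixels <- which(pixels)
  }
  rc <- indexToRc(pixels, imageDim)
  new("CellROI", cellId = as.integer(cellId), pixels = as.integer(sort(pixels)),
      imageDim = as.integer(imageDim),
      centroid = c(mean(rc[, 1L]), mean(rc[, 2L])))
}

#' @describeIn CellROI-class mask as a logical matrix.
#' @param x a CellROI.
#' @export
roiMask <- function(x) {
  m <- matrix(FALSE, x@imageDim[1L], x@imageDim[2L])
  m[x@pixels] <- TRUE
  m
}

#' @describeIn CellROI-class infection flag (NA until flagged).
#' @export
isInfected <- function(x) x@infected

## ---------------------------------------------------------------------------
## OtsuResult
## ---------------------------------------------------------------------------

#' Result of Otsu histogram thresholding
#'
#' @slot threshold threshold in intensity units (the upper edge of the
#'   selected bin); class 0 is "<= threshold".
#' @slot betweenClassVariance maximized between-class variance, counts^2.
#' @slot histogram bin counts.
#' @slot breaks bin edges (length `nBins + 1`).
#' @exportClass OtsuResult
setClass(
  "OtsuResult",
  slots = c(
    threshold = "numeric",
    betweenClassVariance = "numeric",
    histogram = "numeric",
    breaks = "numeric"
  )
)

#' @describeIn OtsuResult-class threshold in intensity units.
#' @param x an OtsuResult.
#' @export
threshold <- function(x) x@threshold

## ---------------------------------------------------------------------------
## AxialProfile
## ---------------------------------------------------------------------------

#' An axial fluorescence intensity profile
#'
#' Reporter intensity sampled at `nPoints` evenly spaced positions along a
#' cell's long axis. `positions` run from 0 ("initial measured end") to 1,
#' so resampling itself implements normalization by cell length.
#' [normalizeProfile()] fills `valuesNorm = valuesRaw / anchor`, where
#' `anchor` is the mean raw intensity over the first `anchorFrac` of
#' positions — the intensity at the initial measured end.
#'
#' @slot cellId integer id of the parent cell.
#' @slot positions strictly increasing, first 0, last 1.
#' @slot valuesRaw raw interpolated intensities, counts.
#' @slot valuesNorm end-anchored values (`NA` until normalized).
#' @slot anchor anchor intensity, counts (`NA` until normalized).
#' @slot anchorFrac fraction of positions in the anchor window.
#' @exportClass AxialProfile
setClass(
  "AxialProfile",
  slots = c(
    cellId = "integer",
    positions = "numeric",
    valuesRaw = "numeric",
    valuesNorm = "numeric",
    anchor = "numeric",
    anchorFrac = "numeric"
  ),
  prototype = list(
    valuesNorm = NA_real_,
    anchor = NA_real_,
    anchorFrac = NA_real_
  )
)

setValidity("AxialProfile", function(object) {
  msg <- character(0)
  p <- object@positions
  if (length(p) < 3L) msg <- c(msg, "need at least 3 positions")
  if (length(p) >= 2L) {
    if (any(diff(p) <= 0)) msg <- c(msg, "positions must be strictly increasing")
    if (abs(p[1L]) > 1e-12 || abs(p[length(p)] - 1) > 1e-12) {
      msg <- c(msg, "positions must start at 0 and end at 1")
    }
  }
  if (length(object@valuesRaw) != length(p)) {
    msg <- c(msg, "valuesRaw and positions lengths differ")
  }
  if (!anyNA(object@valuesNorm) && !is.na(object@anchor)) {
    if (length(object@valuesNorm) != length(p)) {
      msg <- c(msg, "valuesNorm and positions lengths differ")
    } else if (max(abs(object@valuesNorm * object@anchor -
                       object@valuesRaw)) > 1e-8 * max(1, object@anchor)) {
      msg <- c(msg, "valuesNorm * anchor must reproduce valuesRaw")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn AxialProfile-class profile as a data.frame
#'   (position, valueRaw, valueNorm).
#' @param x an AxialProfile.
#' @export
profileTable <- function(x) {
  data.frame(
    cellId = x@cellId,
    position = x@positions,
    valueRaw = x@valuesRaw,
    valueNorm = if (length(x@valuesNorm) == length(x@positions)) {
      x@valuesNorm
    } else {
      rep(NA_real_, length(x@positions))
    }
  )
}

## ---------------------------------------------------------------------------
## PhenotypeCall
## ---------------------------------------------------------------------------

#' A per-cell localization phenotype call
#'
#' `score` is the ratio of the mean normalized intensity over the central
#' window of the profile to the mean over the two pooled end windows.
#' `score >= tHi` calls the reporter nucleus-imported, `score <= tLo`
#' nucleus-excluded, anything between is mixed/ambiguous.
#'
#' @slot cellId integer id.
#' @slot score center/ends intensity ratio (dimensionless).
#' @slot call one of `"imported"`, `"excluded"`, `"mixed_ambiguous"`.
#' @slot tHi,tLo thresholds used (`tLo < 1 < tHi`).
#' @exportClass PhenotypeCall
setClass(
  "PhenotypeCall",
  slots = c(
    cellId = "integer",
    score = "numeric",
    call = "character",
    tHi = "numeric",
    tLo = "numeric"
  )
)

setValidity("PhenotypeCall", function(object) {
  msg <- character(0)
  if (!object@call %in% CALLS) {
    msg <- c(msg, sprintf("call must be one of %s", paste(CALLS, collapse = ", ")))
  }
  if (!(object@tLo < 1 && 1 < object@tHi)) msg <- c(msg, "need tLo < 1 < tHi")
  expected <- if (object@score >= object@tHi) "imported"
  else if (object@score <= object@tLo) "excluded"
  else "mixed_ambiguous"
  if (object@call != expected) msg <- c(msg, "call inconsistent with score")
  if (length(msg)) msg else TRUE
})

#' @describeIn PhenotypeCall-class the center/ends score.
#' @param x a PhenotypeCall.
#' @export
callScore <- function(x) x@score

#' @describeIn PhenotypeCall-class the categorical call.
#' @export
callLabel <- function(x) x@call

## ---------------------------------------------------------------------------
## ProfileEnsemble
## ---------------------------------------------------------------------------

#' An ensemble (strain/condition) of axial profiles
#'
#' Positionwise arithmetic mean and standard deviation of the member
#' profiles' normalized values, as used to plot per-condition average
#' tracings.
#'
#' @slot positions common position grid.
#' @slot mean positionwise mean of members' `valuesNorm`.
#' @slot sd positionwise standard deviation (0 for a single member).
#' @slot n number of member profiles.
#' @exportClass ProfileEnsemble
setClass(
  "ProfileEnsemble",
  slots = c(
    positions = "numeric",
    mean = "numeric",
    sd = "numeric",
    n = "integer"
  )
)

#' @describeIn ProfileEnsemble-class ensemble as a data.frame
#'   (position, mean, sd, n).
#' @param x a ProfileEnsemble.
#' @export
ensembleTable <- function(x) {
  data.frame(position = x@positions, mean = x@mean, sd = x@sd, n = x@n)
}

## ---------------------------------------------------------------------------
## NucleusQuant
## ---------------------------------------------------------------------------

#' Per-cell DAPI nucleus quantification
#'
#' The phage-nucleus mask is the largest above-Otsu-threshold component of
#' the in-ROI DNA channel; `meanDapi` is the mean raw intensity inside the
#' mask and `background` the mean over the in-ROI complement of the mask.
#' Neither is background-subtracted; the difference is available as
#' `meanMinusBackground()`.
#'
#' @slot cellId integer id.
#' @slot nucleusPixels 1-based linear indices of the nucleus mask (always
#'   a subset of the cell ROI).
#' @slot imageDim (rows, cols) of the parent image.
#' @slot meanDapi mean raw DNA-channel intensity in the mask, counts.
#' @slot background mean raw intensity over the in-ROI complement, counts.
#' @slot maskArea nucleus mask area, px^2.
#' @exportClass NucleusQuant
setClass(
  "NucleusQuant",
  slots = c(
    cellId = "integer",
    nucleusPixels = "integer",
    imageDim = "integer",
    meanDapi = "numeric",
    background = "numeric",
    maskArea = "integer"
  )
)

setValidity("NucleusQuant", function(object) {
  if (object@maskArea < 1L) "maskArea must be >= 1" else TRUE
})

#' @describeIn NucleusQuant-class background-subtracted in-mask mean.
#' @param x a NucleusQuant.
#' @export
meanMinusBackground <- function(x) x@meanDapi - x@background

#' @describeIn NucleusQuant-class nucleus mask as a logical matrix.
#' @export
nucleusMask <- function(x) {
  m <- matrix(FALSE, x@imageDim[1L], x@imageDim[2L])
  m[x@nucleusPixels] <- TRUE
  m
}

## ---------------------------------------------------------------------------
## GroupComparison
## ---------------------------------------------------------------------------

#' Comparison of per-cell nucleus intensities between two groups
#'
#' Shared equal-width histogram over the pooled range of per-cell mean
#' nucleus intensities, per-group summary statistics, and the percent
#' difference of group means relative to the reference (first) group:
#' `100 * (meanRef - meanOther) / meanRef`.
#'
#' @slot labels group labels, reference first.
#' @slot n per-group cell counts.
#' @slot means,sds per-group mean and sd of the per-cell values.
#' @slot percentDifference percent difference relative to the reference.
#' @slot breaks shared histogram bin edges.
#' @slot counts nBins x 2 matrix of per-group bin counts.
#' @exportClass GroupComparison
setClass(
  "GroupComparison",
  slots = c(
    labels = "character",
    n = "integer",
    means = "numeric",
    sds = "numeric",
    percentDifference = "numeric",
    breaks = "numeric",
    counts = "matrix"
  )
)

#' @describeIn GroupComparison-class percent difference of group means.
#' @param x a GroupComparison.
#' @export
percentDifference <- function(x) x@percentDifference

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "OpticsModel", function(object) {
  cat(sprintf(
    "OpticsModel: %g nm/px, PSF sigma %g nm, offset %g, read noise %g, photon scale %g\n",
    object@pixelSize, object@psfSigma, object@cameraOffset,
    object@readNoiseSd, object@photonScale))
})

setMethod("show", "CellSpec", function(object) {
  cat(sprintf(
    "CellSpec: %s%s, %.2g x %.2g um at (%.1f, %.1f), theta=%.2f rad, contrast %.2g\n",
    object@phenotype, if (object@infected) " (infected)" else " (uninfected)",
    object@length, object@width, object@center[1], object@center[2],
    object@orientation, object@gfpContrast))
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px, %d cells, seed %d\n",
              object@imageShape[1], object@imageShape[2],
              length(object@cells), object@seed))
})

setMethod("show", "SceneRender", function(object) {
  cat(sprintf("SceneRender: channels [%s], %d x %d px, %d cells, noise %s\n",
              paste(names(object@images), collapse = ", "),
              nrow(object@images[[1]]), ncol(object@images[[1]]),
              length(object@groundTruth$cells),
              if (object@noise) "on" else "off"))
})

setMethod("show", "CellROI", function(object) {
  cat(sprintf(
    "CellROI %d: %d px, centroid (%.1f, %.1f), length %s px, infected: %s\n",
    object@cellId, length(object@pixels),
    object@centroid[1], object@centroid[2],
    if (is.na(object@lengthPx)) "unset" else sprintf("%.1f", object@lengthPx),
    object@infected))
})

setMethod("show", "OtsuResult", function(object) {
  cat(sprintf("OtsuResult: threshold %.4g (between-class variance %.4g, %d bins)\n",
              object@threshold, object@betweenClassVariance,
              length(object@histogram)))
})

setMethod("show", "AxialProfile", function(object) {
  cat(sprintf("AxialProfile (cell %d): %d points%s\n",
              object@cellId, length(object@positions),
              if (is.na(object@anchor)) " (raw)"
              else sprintf(", anchor %.4g", object@anchor)))
})

setMethod("show", "PhenotypeCall", function(object) {
  cat(sprintf("PhenotypeCall (cell %d): %s (score %.3f; tLo %.2f, tHi %.2f)\n",
              object@cellId, object@call, object@score, object@tLo, object@tHi))
})

setMethod("show", "ProfileEnsemble", function(object) {
  cat(sprintf("ProfileEnsemble: n = %d, %d positions, central mean %.3f\n",
              object@n, length(object@positions),
              object@mean[ceiling(length(object@mean) / 2)]))
})

setMethod("show", "NucleusQuant", function(object) {
  cat(sprintf(
    "NucleusQuant (cell %d): mask %d px, mean DAPI %.1f, background %.1f\n",
    object@cellId, object@maskArea, object@meanDapi, object@background))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf(
    "GroupComparison: %s (n=%d, mean %.1f) vs %s (n=%d, mean %.1f): %.1f%% difference\n",
    object@labels[1], object@n[1], object@means[1],
    object@labels[2], object@n[2], object@means[2],
    object@percentDifference))
})
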