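## Axial intensity profiles: extraction along the long axis, length and
## end-anchored normalization, phenotype classification, orientation
## handling, ensemble averaging and population fractions.

#' Extract a raw axial intensity profile
#'
#' Samples the reporter image by bilinear interpolation at `nPoints`
#' evenly spaced subpixel positions along the cell's long axis (from the
#' initial measured end `axisP0` to `axisP1`). Sampling on a fixed
#' `[0, 1]` grid is what normalizes the profile by cell length. With
#' `lineWidth > 1`, each axial position is averaged over `lineWidth`
#' samples placed perpendicular to the axis at one-pixel spacing,
#' centered on the line.
#'
#' @param gfp reporter-channel image matrix.
#' @param roi a [CellROI] with its axis set.
#' @param nPoints number of evenly spaced sample positions.
#' @param lineWidth averaging width perpendicular to the axis, px.
#' @return a raw [AxialProfile] (`valuesNorm` unset).
#' @examples
#' img <- matrix(100, 40, 40)
#' m <- matrix(FALSE, 40, 40); m[18:22, 5:35] <- TRUE
#' p <- extractProfile(img, longAxis(cellROI(1, m)), nPoints = 11)
#' p@valuesRaw
#' @export
extractProfile <- function(gfp, roi, nPoints = 101L, lineWidth = 1L) {
  if (nPoints < 3L) stopWith("profileError", "nPoints must be >= 3")
  if (anyNA(roi@axisP0) || anyNA(roi@axisP1)) {
    stopWith("profileError", "roi has no long axis; run longAxis() first")
  }
  if (roi@lengthPx < 3) {
    stopWith("profileError",
             sprintf("axis of cell %d is shorter than 3 px", roi@cellId))
  }
  s <- seq(0, 1, length.out = nPoints)
  u <- (roi@axisP1 - roi@axisP0) / roi@lengthPx
  v <- c(-u[2L], u[1L]) # unit perpendicular
  offsets <- seq_len(lineWidth) - (lineWidth + 1) / 2
  vals <- matrix(0, nPoints, length(offsets))
  for (k in seq_along(offsets)) {
    rows <- roi@axisP0[1L] + s * (roi@axisP1[1L] - roi@axisP0[1L]) +
      offsets[k] * v[1L]
    cols <- roi@axisP0[2L] + s * (roi@axisP1[2L] - roi@axisP0[2L]) +
      offsets[k] * v[2L]
    vals[, k] <- bilinearSample(gfp, rows, cols)
  }
  new("AxialProfile", cellId = roi@cellId, positions = s,
      valuesRaw = rowMeans(vals))
}

#' Anchor a profile to its initial-end intensity
#'
#' Divides the raw values by the anchor intensity: the mean of
#' `valuesRaw` over the first `max(1, ceiling(anchorFrac * nPoints))`
#' positions, i.e. the reporter intensity at the initial measured end of
#' the cell. By construction the mean of `valuesNorm` over the anchor
#' window is exactly 1, and the normalized profile is invariant to any
#' overall gain applied to the image.
#'
#' @param profile a raw [AxialProfile].
#' @param anchorFrac fraction of positions forming the anchor window.
#' @return the [AxialProfile] with `valuesNorm` and `anchor` set.
#' @examples
#' p <- new("AxialProfile", cellId = 1L,
#'          positions = seq(0, 1, length.out = 5),
#'          valuesRaw = c(100, 150, 200, 150, 100))
#' normalizeProfile(p, anchorFrac = 0.05)@valuesNorm
#' @export
normalizeProfile <- function(profile, anchorFrac = 0.05) {
  n <- length(profile@positions)
  k <- max(1L, ceiling(anchorFrac * n))
  anchor <- mean(profile@valuesRaw[seq_len(k)])
  if (!is.finite(anchor) || anchor <= 0) {
    stopWith("normalizationError", sprintf(
      "cell %d: anchor intensity %.3g is not positive", profile@cellId, anchor))
  }
  profile@anchor <- anchor
  profile@anchorFrac <- anchorFrac
  profile@valuesNorm <- profile@valuesRaw / anchor
  validObject(profile)
  profile
}

## Index sets for the classification windows. The end windows are inset
## from the cell tips by `endMargin` so that the PSF-driven intensity
## falloff at the poles does not bias the end estimate.
classifyWindows <- function(positions, centerFrac, endFrac, endMargin) {
  eps <- 1e-9
  center <- which(abs(positions - 0.5) <= centerFrac / 2 + eps)
  ends <- which(
    (positions >= endMargin - eps &
       positions <= endMargin + endFrac + eps) |
      (positions >= 1 - endMargin - endFrac - eps &
         positions <= 1 - endMargin + eps))
  list(center = center, ends = ends)
}

#' Classify the localization phenotype of one cell
#'
#' Computes `score` = (mean normalized intensity over the central
#' `centerFrac` of positions) / (mean over the two pooled end windows of
#' width `endFrac`, inset from the cell poles by `endMargin`), and calls
#' the reporter `imported` when `score >= tHi`, `excluded` when
#' `score <= tLo`, and `mixed_ambiguous` otherwise. The score pools both
#' ends symmetrically, so it is invariant to reversing the profile.
#' Intended for cells flagged infected (the phenotype is only defined
#' relative to a phage nucleus).
#'
#' @param profile a normalized [AxialProfile].
#' @param centerFrac width of the central window (fraction of positions).
#' @param endFrac width of each end window.
#' @param endMargin inset of the end windows from the profile ends.
#' @param tHi,tLo call thresholds (`tLo < 1 < tHi`).
#' @return a [PhenotypeCall].
#' @examples
#' flat <- normalizeProfile(new("AxialProfile", cellId = 1L,
#'   positions = seq(0, 1, length.out = 101), valuesRaw = rep(5, 101)))
#' callLabel(classifyLocalization(flat))
#' @export
classifyLocalization <- function(profile, centerFrac = 0.2, endFrac = 0.1,
                                 endMargin = 0.1, tHi = 1.2, tLo = 0.8) {
  if (anyNA(profile@valuesNorm) ||
      length(profile@valuesNorm) != length(profile@positions)) {
    stopWith("classificationError",
             "profile is not normalized; run normalizeProfile() first")
  }
  w <- classifyWindows(profile@positions, centerFrac, endFrac, endMargin)
  denom <- mean(profile@valuesNorm[w$ends])
  if (!is.finite(denom) || denom <= 0) {
    stopWith("classificationError", sprintf(
      "cell %d: end-window mean %.3g is not positive", profile@cellId, denom))
  }
  score <- mean(profile@valuesNorm[w$center]) / denom
  call <- if (score >= tHi) "imported" else if (score <= tLo) "excluded"
  else "mixed_ambiguous"
  new("PhenotypeCall", cellId = profile@cellId, score = score, call = call,
      tHi = tHi, tLo = tLo)
}

#' Orient profiles so the brighter end half comes first
#'
#' Rod-shaped cells have no intrinsic polarity, so the "initial measured
#' end" of an automatically extracted profile is an arbitrary (if
#' deterministic) choice. When enabled, each profile whose second half is
#' brighter than its first (by raw mean) is reversed, then re-anchored.
#' Classification is invariant to this (the score pools both ends), so
#' orientation only affects how per-cell tracings line up in plots.
#'
#' @param profiles list of [AxialProfile] (raw or normalized).
#' @param enabled logical; if `FALSE` the input is returned unchanged.
#' @return list of [AxialProfile] in the same order.
#' @export
orientProfiles <- function(profiles, enabled = TRUE) {
  if (!enabled) return(profiles)
  lapply(profiles, function(p) {
    first <- mean(p@valuesRaw[p@positions < 0.5])
    second <- mean(p@valuesRaw[p@positions > 0.5])
    if (second > first) {
      wasNormalized <- !anyNA(p@valuesNorm) && !is.na(p@anchor)
      anchorFrac <- p@anchorFrac
      p@valuesRaw <- rev(p@valuesRaw)
      p@valuesNorm <- NA_real_
      p@anchor <- NA_real_
      p@anchorFrac <- NA_real_
      if (wasNormalized) p <- normalizeProfile(p, anchorFrac)
    }
    p
  })
}

#' Average normalized profiles into an ensemble
#'
#' Positionwise arithmetic mean and standard deviation of the members'
#' normalized values — the per-condition "average tracing". All members
#' must share the same position grid.
#'
#' @param members list of normalized [AxialProfile]s.
#' @return a [ProfileEnsemble].
#' @examples
#' mk <- function(v) normalizeProfile(new("AxialProfile", cellId = 1L,
#'   positions = c(0, 0.5, 1), valuesRaw = v), anchorFrac = 0.05)
#' averageProfiles(list(mk(c(1, 2, 1)), mk(c(1, 0, 1))))@mean
#' @export
averageProfiles <- function(members) {
  if (length(members) == 0L) {
    stopWith("ensembleError", "no profiles to average")
  }
  nPoints <- length(members[[1L]]@positions)
  for (m in members) {
    if (length(m@positions) != nPoints ||
        max(abs(m@positions - members[[1L]]@positions)) > 1e-9) {
      stopWith("ensembleError", "members do not share a common position grid")
    }
    if (anyNA(m@valuesNorm) || length(m@valuesNorm) != nPoints) {
      stopWith("ensembleError", "all members must be normalized")
    }
  }
  vals <- vapply(members, function(m) m@valuesNorm, numeric(nPoints))
  vals <- matrix(vals, nrow = nPoints)
  n <- length(members)
  new("ProfileEnsemble",
      positions = members[[1L]]@positions,
      mean = rowMeans(vals),
      sd = if (n == 1L) rep(0, nPoints) else apply(vals, 1L, stats::sd),
      n = as.integer(n))
}

#' Population fractions of localization phenotypes
#'
#' Tabulates per-cell calls into fractions over
#' `imported` / `excluded` / `mixed_ambiguous` (summing to 1) with the
#' population size `n` — the quantity behind statements such as
#' "excluded in 100% of cells (n = 177)".
#'
#' @param calls list of [PhenotypeCall]s.
#' @return list with `fractions` (named, sums to 1), `counts`, and `n`.
#' @examples
#' calls <- lapply(1:4, function(i) new("PhenotypeCall", cellId = i,
#'   score = 0.5, call = "excluded", tHi = 1.2, tLo = 0.8))
#' populationFractions(calls)$fractions
#' @export
populationFractions <- function(calls) {
  if (length(calls) == 0L) {
    stopWith("emptyPopulationError", "no phenotype calls supplied")
  }
  labels <- vapply(calls, callLabel, character(1))
  counts <- vapply(CALLS, function(cl) sum(labels == cl), numeric(1))
  list(fractions = counts / length(calls), counts = counts,
       n = length(calls))
}
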