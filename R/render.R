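## Synthetic scene rendering: spherocylinder cells with an optional
## phage-nucleus disk, Gaussian PSF blur, Poisson shot noise and Gaussian
## read noise on a constant camera offset.

## Cell geometry in pixel units. Returns the unit axis vector, the
## half-length of the central segment, tip endpoints and nucleus geometry.
cellGeometry <- function(cell, optics) {
  umPerPx <- optics@pixelSize / 1000
  lengthPx <- cell@length / umPerPx
  widthPx <- cell@width / umPerPx
  u <- c(sin(cell@orientation), cos(cell@orientation)) # (d_row, d_col)
  halfSeg <- (lengthPx - widthPx) / 2
  tip0 <- cell@center - u * lengthPx / 2
  tip1 <- cell@center + u * lengthPx / 2
  nucleusCenter <- tip0 + u * cell@nucleusAxialPos * lengthPx
  list(
    u = u, lengthPx = lengthPx, widthPx = widthPx, halfSeg = halfSeg,
    seg0 = cell@center - u * halfSeg, seg1 = cell@center + u * halfSeg,
    tip0 = tip0, tip1 = tip1,
    nucleusCenter = nucleusCenter,
    nucleusRadius = cell@nucleusRadiusFrac * widthPx / 2
  )
}

## Pixel-center masks for one cell within its bounding box. Returns NULL
## geometry plus logical matrices over the full image for simplicity of
## downstream bookkeeping; computation is restricted to the bounding box.
cellMasks <- function(cell, optics, imageShape) {
  g <- cellGeometry(cell, optics)
  pad <- g$widthPx / 2 + 2
  r0 <- floor(min(g$tip0[1], g$tip1[1]) - pad)
  r1 <- ceiling(max(g$tip0[1], g$tip1[1]) + pad)
  c0 <- floor(min(g$tip0[2], g$tip1[2]) - pad)
  c1 <- ceiling(max(g$tip0[2], g$tip1[2]) + pad)
  if (r0 < 0 || c0 < 0 || r1 > imageShape[1] - 1 || c1 > imageShape[2] - 1) {
    stopWith("geometryError", sprintf(
      "cell footprint at (%.1f, %.1f) extends outside the %d x %d image",
      cell@center[1], cell@center[2], imageShape[1], imageShape[2]))
  }
  rows <- r0:r1
  cols <- c0:c1
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  ## distance from each pixel center to the central axis segment
  dr <- rr - g$seg0[1]
  dc <- cc - g$seg0[2]
  segLen2 <- sum((g$seg1 - g$seg0)^2)
  if (segLen2 > 0) {
    t <- (dr * (g$seg1[1] - g$seg0[1]) + dc * (g$seg1[2] - g$seg0[2])) / segLen2
    t <- pmin(pmax(t, 0), 1)
  } else {
    t <- 0
  }
  px <- g$seg0[1] + t * (g$seg1[1] - g$seg0[1])
  py <- g$seg0[2] + t * (g$seg1[2] - g$seg0[2])
  d <- sqrt((rr - px)^2 + (cc - py)^2)
  inside <- d <= g$widthPx / 2
  outline <- inside & d > g$widthPx / 2 - 1
  nucleus <- if (cell@infected) {
    inside & (sqrt((rr - g$nucleusCenter[1])^2 +
                   (cc - g$nucleusCenter[2])^2) <= g$nucleusRadius)
  } else {
    inside & FALSE
  }
  list(
    geometry = g,
    rowRange = c(r0, r1) + 1L, colRange = c(c0, c1) + 1L, # 1-based matrix slices
    inside = inside, outline = outline, nucleus = nucleus
  )
}

## Emitter density of one cell in one channel, on its bounding-box grid.
cellDensity <- function(cell, masks, channel) {
  d <- matrix(0, nrow(masks$inside), ncol(masks$inside))
  switch(channel,
    gfp = {
      d[masks$inside] <- cell@gfpCytoplasmLevel
      d[masks$nucleus] <- cell@gfpContrast * cell@gfpCytoplasmLevel
    },
    dapi = {
      d[masks$inside] <- cell@dapiBackgroundLevel
      d[masks$nucleus] <- cell@dapiNucleusLevel
    },
    membrane = {
      d[masks$outline] <- cell@membraneLevel
    }
  )
  d
}

checkOverlaps <- function(cells, optics) {
  n <- length(cells)
  if (n < 2L) return(invisible(TRUE))
  geoms <- lapply(cells, cellGeometry, optics = optics)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      minDist <- (geoms[[i]]$widthPx + geoms[[j]]$widthPx) / 2
      d <- segmentDistance(geoms[[i]]$seg0, geoms[[i]]$seg1,
                           geoms[[j]]$seg0, geoms[[j]]$seg1)
      if (d <= minDist) {
        stopWith("overlapError",
                 sprintf("cells %d and %d have overlapping footprints", i, j))
      }
    }
  }
  invisible(TRUE)
}

#' Render a synthetic multi-channel micrograph
#'
#' Renders the field of view described by a [SceneSpec]: each cell is
#' painted as a 2-D spherocylinder of emitter density (with, for infected
#' cells, a circular nucleus disk on the long axis whose reporter density
#' is `gfpContrast` times the cytoplasm and whose DNA-stain density is
#' `dapiNucleusLevel`; the membrane channel paints only the one-pixel cell
#' outline), convolved with the Gaussian PSF, scaled by the photon scale,
#' and — when `noise = TRUE` — Poisson-sampled, offset, perturbed by
#' Gaussian read noise, clipped at zero and rounded to integer counts.
#' With `noise = FALSE` the expected (continuous) counts plus offset are
#' returned, which is the noiseless limit used by many unit tests.
#'
#' Rendering is deterministic: the same SceneSpec (including its seed)
#' produces bit-identical images.
#'
#' @param spec a [SceneSpec].
#' @param noise logical; apply the Poisson + read-noise camera model.
#' @return a [SceneRender] with channel images (fixed order gfp, dapi,
#'   membrane) and pixel-level ground truth.
#' @examples
#' sp <- SceneSpec(imageShape = c(100, 100),
#'                 cells = list(CellSpec(center = c(50, 50))), seed = 1)
#' rs <- renderScene(sp)
#' range(sceneImages(rs)$gfp)
#' @export
renderScene <- function(spec, noise = TRUE) {
  validObject(spec)
  for (cell in spec@cells) validObject(cell)
  optics <- spec@optics
  shape <- spec@imageShape
  checkOverlaps(spec@cells, optics)

  density <- lapply(CHANNELS, function(ch) matrix(0, shape[1], shape[2]))
  names(density) <- CHANNELS
  label <- matrix(0L, shape[1], shape[2])
  gtCells <- vector("list", length(spec@cells))

  for (i in seq_along(spec@cells)) {
    cell <- spec@cells[[i]]
    masks <- cellMasks(cell, optics, shape)
    rows <- masks$rowRange[1]:masks$rowRange[2]
    cols <- masks$colRange[1]:masks$colRange[2]
    for (ch in CHANNELS) {
      density[[ch]][rows, cols] <-
        density[[ch]][rows, cols] + cellDensity(cell, masks, ch)
    }
    sub <- label[rows, cols]
    sub[masks$inside] <- i
    label[rows, cols] <- sub
    ## ground truth: linear indices in the full image
    boxIdx <- which(masks$inside)
    boxDim <- dim(masks$inside)
    boxRc <- indexToRc(boxIdx, boxDim)
    fullIdx <- rcToIndex(
      cbind(boxRc[, 1L] + masks$rowRange[1] - 1L,
            boxRc[, 2L] + masks$colRange[1] - 1L), shape)
    nucBoxIdx <- which(masks$nucleus)
    nucRc <- indexToRc(nucBoxIdx, boxDim)
    nucIdx <- if (length(nucBoxIdx)) {
      rcToIndex(cbind(nucRc[, 1L] + masks$rowRange[1] - 1L,
                      nucRc[, 2L] + masks$colRange[1] - 1L), shape)
    } else {
      integer(0)
    }
    gtCells[[i]] <- list(
      id = i,
      pixels = fullIdx,
      nucleusPixels = nucIdx,
      axisP0 = masks$geometry$tip0,
      axisP1 = masks$geometry$tip1,
      lengthPx = masks$geometry$lengthPx,
      widthPx = masks$geometry$widthPx,
      phenotype = cell@phenotype,
      infected = cell@infected,
      meanDensity = vapply(CHANNELS, function(ch) {
        mean(cellDensity(cell, masks, ch)[masks$inside])
      }, numeric(1))
    )
  }

  sigmaPx <- optics@psfSigma / optics@pixelSize
  expected <- lapply(density, function(d) {
    optics@photonScale * safeGblur(d, sigmaPx)
  })

  images <- if (noise) {
    withSeed(spec@seed, {
      lapply(expected, function(e) {
        counts <- stats::rpois(length(e), pmax(e, 0)) + optics@cameraOffset +
          stats::rnorm(length(e), 0, optics@readNoiseSd)
        matrix(round(pmax(counts, 0)), nrow(e), ncol(e))
      })
    })
  } else {
    lapply(expected, function(e) e + optics@cameraOffset)
  }

  new("SceneRender", images = images,
      groundTruth = list(cells = gtCells, label = label),
      spec = spec, noise = noise)
}

#' Generate a synthetic cell population as renderable scenes
#'
#' Draws `n` cells whose localization phenotypes follow `phenotypeMix` (in
#' expectation; realized labels are recorded in the ground truth), jitters
#' cell length and width around a template, orients each cell uniformly at
#' random, and places cells in one or more fields of view by rejection
#' sampling so that no two footprints overlap (up to `maxAttempts`
#' placement attempts per cell, then an overlap error). Everything is
#' deterministic given `seed`; scene-level noise seeds are derived from it
#' by a fixed counter scheme.
#'
#' @param n number of cells.
#' @param phenotypeMix named fractions over `imported`, `excluded`,
#'   `uniform`; must sum to 1 (within 1e-9).
#' @param baseCell template [CellSpec] (its phenotype/contrast are
#'   overridden per drawn label).
#' @param jitter relative standard deviation applied to length and width.
#' @param seed integer seed.
#' @param imageShape per-scene image shape.
#' @param cellsPerScene maximum number of cells per field of view.
#' @param importedContrast,excludedContrast reporter contrast assigned to
#'   imported / excluded cells (uniform cells get 1).
#' @param optics [OpticsModel] shared by all generated scenes.
#' @param maxAttempts placement attempts per cell before failing.
#' @return list of [SceneSpec]s jointly containing exactly `n` cells.
#' @examples
#' scenes <- makePopulation(10, c(excluded = 1), seed = 1,
#'                          imageShape = c(300, 300), cellsPerScene = 10)
#' sum(lengths(lapply(scenes, slot, "cells")))
#' @export
makePopulation <- function(n, phenotypeMix,
                           baseCell = CellSpec(),
                           jitter = 0.1,
                           seed = 1,
                           imageShape = c(600L, 600L),
                           cellsPerScene = 24L,
                           importedContrast = 3,
                           excludedContrast = 0.2,
                           optics = OpticsModel(),
                           maxAttempts = 100L) {
  if (n < 1) stopWith("configError", "n must be >= 1")
  if (is.null(names(phenotypeMix)) ||
      !all(names(phenotypeMix) %in% PHENOTYPES)) {
    stopWith("configError", sprintf(
      "phenotypeMix must be named with a subset of {%s}",
      paste(PHENOTYPES, collapse = ", ")))
  }
  if (any(phenotypeMix < 0) || abs(sum(phenotypeMix) - 1) > 1e-9) {
    stopWith("configError", "phenotypeMix fractions must be >= 0 and sum to 1")
  }
  withSeed(seed, {
    labels <- if (length(phenotypeMix) == 1L) {
      rep(names(phenotypeMix), n)
    } else {
      sample(names(phenotypeMix), n, replace = TRUE, prob = phenotypeMix)
    }
    nScenes <- ceiling(n / cellsPerScene)
    sceneOf <- rep(seq_len(nScenes), each = cellsPerScene)[seq_len(n)]
    scenes <- vector("list", nScenes)
    for (s in seq_len(nScenes)) {
      idx <- which(sceneOf == s)
      cells <- vector("list", length(idx))
      placedGeoms <- list()
      refOptics <- optics
      for (k in seq_along(idx)) {
        label <- labels[idx[k]]
        len <- max(baseCell@width,
                   baseCell@length * (1 + jitter * truncNorm1()))
        wid <- max(0.4, baseCell@width * (1 + jitter * truncNorm1()))
        if (len < wid) len <- wid
        contrast <- switch(label,
                           imported = importedContrast,
                           excluded = excludedContrast,
                           uniform = 1)
        placed <- FALSE
        for (attempt in seq_len(maxAttempts)) {
          orient <- stats::runif(1, 0, pi)
          lengthPx <- len * 1000 / refOptics@pixelSize
          widthPx <- wid * 1000 / refOptics@pixelSize
          margin <- lengthPx / 2 + widthPx / 2 + 3
          if (2 * margin >= min(imageShape)) {
            stopWith("geometryError",
                     "imageShape too small for the requested cells")
          }
          center <- c(stats::runif(1, margin, imageShape[1] - 1 - margin),
                      stats::runif(1, margin, imageShape[2] - 1 - margin))
          cand <- CellSpec(
            center = center, length = len, width = wid, orientation = orient,
            infected = baseCell@infected,
            nucleusRadiusFrac = baseCell@nucleusRadiusFrac,
            nucleusAxialPos = baseCell@nucleusAxialPos,
            phenotype = label, gfpContrast = contrast,
            gfpCytoplasmLevel = baseCell@gfpCytoplasmLevel,
            dapiNucleusLevel = baseCell@dapiNucleusLevel,
            dapiBackgroundLevel = baseCell@dapiBackgroundLevel,
            membraneLevel = baseCell@membraneLevel)
          g <- cellGeometry(cand, refOptics)
          ok <- TRUE
          ## clearance keeps blurred neighbors separable downstream
          psfPad <- 4 * refOptics@psfSigma / refOptics@pixelSize
          for (pg in placedGeoms) {
            clearance <- (g$widthPx + pg$widthPx) / 2 + 2 + psfPad
            if (segmentDistance(g$seg0, g$seg1, pg$seg0, pg$seg1) <= clearance) {
              ok <- FALSE
              break
            }
          }
          if (ok) {
            cells[[k]] <- cand
            placedGeoms[[length(placedGeoms) + 1L]] <- g
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stopWith("overlapError", sprintf(
            "could not place cell %d after %d attempts", idx[k], maxAttempts))
        }
      }
      scenes[[s]] <- SceneSpec(imageShape = imageShape, cells = cells,
                               optics = refOptics,
                               seed = deriveSeed(seed, s))
    }
    scenes
  })
}

## Standard normal truncated at +-3 sd; keeps jittered cell dimensions
## physical.
truncNorm1 <- function() {
  max(-3, min(3, stats::rnorm(1)))
}
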