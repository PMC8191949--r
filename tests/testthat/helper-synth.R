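# Shared fixtures: all synthetic, generated in code at test time.

# One centered cell in a small field of view.
singleCellScene <- function(phenotype = "uniform", gfpContrast = 1,
                            psfSigma = 130, cameraOffset = 100,
                            readNoiseSd = 2, imageShape = c(120, 120),
                            seed = 1, ...) {
  SceneSpec(
    imageShape = imageShape,
    cells = list(CellSpec(center = (imageShape - 1) / 2,
                          phenotype = phenotype, gfpContrast = gfpContrast,
                          ...)),
    optics = OpticsModel(psfSigma = psfSigma, cameraOffset = cameraOffset,
                         readNoiseSd = readNoiseSd),
    seed = seed
  )
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# Match each ROI to the ground-truth cell with maximal mask overlap.
matchGroundTruth <- function(rois, gt) {
  vapply(rois, function(roi) {
    ov <- vapply(gt$cells, function(cl) {
      length(intersect(roi@pixels, cl$pixels))
    }, numeric(1))
    which.max(ov)
  }, integer(1))
}

# Independent O(nBins^2) Otsu oracle: recomputes class weights and means
# for every candidate threshold directly from the binned values.
bruteForceOtsu <- function(pixels, nBins = 256L) {
  px <- as.numeric(pixels)
  lo <- min(px); hi <- max(px)
  w <- (hi - lo) / nBins
  bin <- pmin(floor((px - lo) / w) + 1L, nBins)
  mids <- lo + (seq_len(nBins) - 0.5) * w
  n <- length(px)
  sigma <- rep(0, nBins - 1L)
  for (t in seq_len(nBins - 1L)) {
    in0 <- bin <= t
    n0 <- sum(in0)
    if (n0 == 0L || n0 == n) next
    w0 <- n0 / n
    mu0 <- mean(mids[bin[in0]])
    mu1 <- mean(mids[bin[!in0]])
    sigma[t] <- w0 * (1 - w0) * (mu0 - mu1)^2
  }
  tStar <- floor(mean(which(sigma == max(sigma))))
  list(threshold = lo + tStar * w, betweenClassVariance = max(sigma))
}

# A handmade rectangular ROI with its axis established.
rectangleRoi <- function(nr = 40, nc = 40, rows = 18:22, cols = 5:35) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  longAxis(cellROI(1L, m))
}

# Build a normalized profile directly from raw values.
rawProfile <- function(values, cellId = 1L) {
  new("AxialProfile", cellId = as.integer(cellId),
      positions = seq(0, 1, length.out = length(values)),
      valuesRaw = as.numeric(values))
}
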