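test_that("Otsu tie-break on a symmetric two-delta histogram hits the mid bin edge", {
  px <- c(rep(0, 50), rep(255, 50))
  ot <- otsuThreshold(px)
  oracle <- bruteForceOtsu(px)
  expect_equal(threshold(ot), oracle$threshold)
  # frozen from the exhaustive scan: bins 1..255 all tie, mid index 128,
  # upper edge 128 * 255 / 256
  expect_equal(threshold(ot), 127.5)
})

test_that("constant input raises a degenerate-histogram error", {
  expect_error(otsuThreshold(rep(42, 100)),
               class = "degenerateHistogramError")
  expect_error(otsuThreshold(numeric(0)),
               class = "degenerateHistogramError")
})

test_that("Otsu agrees with the brute-force oracle on random histograms", {
  set.seed(424242)
  for (i in 1:200) {
    kind <- i %% 4
    px <- switch(as.character(kind),
      "0" = stats::runif(200, 0, 1000),
      "1" = c(stats::rnorm(150, 100, 10), stats::rnorm(80, 400, 30)),
      "2" = sample(0:20, 300, replace = TRUE),
      "3" = stats::rpois(250, 50))
    if (max(px) == min(px)) next
    nBins <- sample(c(16L, 64L, 256L), 1)
    ot <- otsuThreshold(px, nBins)
    oracle <- bruteForceOtsu(px, nBins)
    expect_equal(threshold(ot), oracle$threshold)
    expect_equal(ot@betweenClassVariance, oracle$betweenClassVariance,
                 tolerance = 1e-9)
  }
})

test_that("segmentation recovers all cells of a noiseless scene with high mask overlap", {
  scenes <- makePopulation(5, c(uniform = 1), seed = 21,
                           imageShape = c(400, 400), cellsPerScene = 5)
  rs <- renderScene(scenes[[1]], noise = FALSE)
  rois <- segmentCells(rs)
  expect_length(rois, 5)
  gt <- groundTruth(rs)
  match <- matchGroundTruth(rois, gt)
  expect_setequal(match, 1:5)
  for (k in seq_along(rois)) {
    expect_gte(jaccard(rois[[k]]@pixels, gt$cells[[match[k]]]$pixels), 0.9)
  }
})

test_that("blank images and border-touching cells are handled", {
  expect_error(segmentCells(matrix(7, 80, 80)), class = "noCellsError")

  interior <- matrix(0, 80, 80)
  interior[30:40, 20:60] <- 1000
  rois <- segmentCells(interior, minArea = 50)
  expect_length(rois, 1)

  touching <- matrix(0, 80, 80)
  touching[1:12, 20:60] <- 1000
  expect_error(
    suppressMessages(segmentCells(touching, minArea = 50)),
    class = "noCellsError")

  both <- interior
  both[1:12, 20:60] <- 1000
  roisBoth <- suppressMessages(segmentCells(both, minArea = 50))
  expect_length(roisBoth, 1)
  expect_gt(min(arrayInd(roisBoth[[1]]@pixels, c(80, 80))[, 1]), 20)
})

test_that("the long axis of a rectangle is its long dimension", {
  roi <- rectangleRoi(30, 60, rows = 11:20, cols = 6:45) # 10 x 40 px
  expect_equal(roi@lengthPx, 39, tolerance = 1e-6)
  # p0 is the lexicographically smaller endpoint, 0-based coordinates
  expect_equal(roi@axisP0, c(14.5, 5), tolerance = 1e-6)
  expect_equal(roi@axisP1, c(14.5, 44), tolerance = 1e-6)
})

test_that("square masks have no defined long axis", {
  m <- matrix(FALSE, 30, 30)
  m[11:20, 11:20] <- TRUE
  expect_error(longAxis(cellROI(1, m)), class = "axisAmbiguousError")
})

test_that("axis recovery is rotation-equivariant within 2 degrees", {
  for (thetaDeg in seq(0, 165, by = 15)) {
    theta <- thetaDeg * pi / 180
    u <- c(sin(theta), cos(theta))
    grid <- expand.grid(r = 0:79, c = 0:79)
    rel <- cbind(grid$r - 39.5, grid$c - 39.5)
    along <- rel %*% u
    perp <- rel %*% c(-u[2], u[1])
    m <- matrix(abs(along) <= 25 & abs(perp) <= 5, 80, 80)
    roi <- longAxis(cellROI(1, m))
    v <- roi@axisP1 - roi@axisP0
    recovered <- atan2(v[1], v[2]) * 180 / pi
    delta <- abs((recovered - thetaDeg + 90) %% 180 - 90)
    expect_lt(delta, 2)
  }
})

test_that("infection flag requires a bright, circular, central DAPI focus", {
  mk <- function(...) {
    rs <- renderScene(singleCellScene(...))
    roi <- longAxis(segmentCells(rs)[[1]])
    isInfected(flagInfected(roi, sceneImages(rs)$dapi))
  }
  expect_true(mk(seed = 31))                          # nucleus at midcell
  expect_false(mk(seed = 32, infected = FALSE))       # uniform DAPI
  expect_false(mk(seed = 33, nucleusAxialPos = 0.1))  # off-center focus
})

test_that("infection calls reach 95% sensitivity and specificity at default SNR", {
  classifyPopulation <- function(infected, seed) {
    scenes <- makePopulation(100, c(uniform = 1),
                             baseCell = CellSpec(infected = infected),
                             seed = seed)
    flags <- logical(0)
    for (sc in scenes) {
      rs <- renderScene(sc)
      rois <- segmentCells(rs)
      for (roi in rois) {
        roi <- tryCatch(longAxis(roi), axisAmbiguousError = function(e) NULL)
        if (is.null(roi)) next
        flags <- c(flags, isInfected(flagInfected(roi, sceneImages(rs)$dapi)))
      }
    }
    flags
  }
  infectedFlags <- classifyPopulation(TRUE, seed = 41)
  uninfectedFlags <- classifyPopulation(FALSE, seed = 42)
  expect_gte(length(infectedFlags), 95)
  expect_gte(length(uninfectedFlags), 95)
  expect_gte(mean(infectedFlags), 0.95)      # sensitivity
  expect_gte(mean(!uninfectedFlags), 0.95)   # specificity
})

test_that("pre-drawn label images round-trip into ROIs", {
  lab <- matrix(0L, 60, 60)
  lab[10:20, 10:40] <- 1L
  lab[35:45, 15:45] <- 2L
  rois <- roisFromLabels(lab)
  expect_length(rois, 2)
  expect_identical(rois[[1]]@pixels, which(lab == 1L))
  path <- tempfile(fileext = ".tif")
  writeLabelTiff(rois, path)
  expect_identical(readLabelTiff(path), matrix(as.integer(lab), 60, 60))
  expect_error(roisFromLabels(matrix(0L, 10, 10)), class = "noCellsError")
})
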