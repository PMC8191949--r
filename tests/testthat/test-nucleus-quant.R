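test_that("nucleus mask and in-mask mean match ground truth on a noiseless cell", {
  # 1-px PSF keeps edge bleed small relative to the disk
  sp <- singleCellScene(psfSigma = 65, readNoiseSd = 0)
  rs <- renderScene(sp, noise = FALSE)
  gt <- groundTruth(rs)$cells[[1]]
  roi <- longAxis(segmentCells(rs)[[1]])
  q <- quantifyNucleus(sceneImages(rs)$dapi, roi)
  expect_gte(jaccard(q@nucleusPixels, gt$nucleusPixels), 0.9)
  inDisk <- mean(sceneImages(rs)$dapi[gt$nucleusPixels])
  expect_equal(q@meanDapi, inDisk, tolerance = 0.05)
  expect_gt(q@meanDapi, q@background)
})

test_that("uniform DAPI within the ROI is degenerate", {
  roi <- rectangleRoi()
  expect_error(quantifyNucleus(matrix(500, 40, 40), roi),
               class = "degenerateHistogramError")
})

test_that("with two bright blobs the mask is the larger one", {
  roi <- rectangleRoi(40, 60, rows = 10:30, cols = 5:55)
  dapi <- matrix(100, 40, 60)
  dapi[15:19, 10:14] <- 5000   # 5x5 blob
  dapi[14:22, 35:43] <- 5000   # 9x9 blob
  q <- quantifyNucleus(dapi, roi)
  expect_identical(q@maskArea, 81L)
  rc <- arrayInd(q@nucleusPixels, c(40, 60))
  expect_true(all(rc[, 2] >= 35 & rc[, 2] <= 43))
})

test_that("an intensity offset shifts mean and background by exactly that offset", {
  rs <- renderScene(singleCellScene(seed = 17))
  roi <- longAxis(segmentCells(rs)[[1]])
  dapi <- sceneImages(rs)$dapi
  q0 <- quantifyNucleus(dapi, roi)
  q1 <- quantifyNucleus(dapi + 57, roi)
  expect_equal(q1@meanDapi, q0@meanDapi + 57)
  expect_equal(q1@background, q0@background + 57)
  expect_equal(meanMinusBackground(q1), meanMinusBackground(q0))
})

test_that("the nucleus mask never leaves the cell ROI", {
  scenes <- makePopulation(6, c(uniform = 1), seed = 23,
                           imageShape = c(400, 400), cellsPerScene = 6)
  rs <- renderScene(scenes[[1]])
  for (roi in segmentCells(rs)) {
    roi <- longAxis(roi)
    q <- quantifyNucleus(sceneImages(rs)$dapi, roi)
    expect_true(all(q@nucleusPixels %in% roi@pixels))
    expect_gte(q@maskArea, 1L)
  }
})

test_that("group comparison reports the percent difference of means", {
  cmp <- compareGroups(rep(7500, 10), rep(6000, 12))
  expect_equal(percentDifference(cmp), 20)
  expect_identical(cmp@n, c(10L, 12L))
  expect_equal(colSums(cmp@counts), c(10, 12))

  same <- compareGroups(c(10, 20, 30), c(10, 20, 30))
  expect_equal(percentDifference(same), 0)

  expect_error(compareGroups(numeric(0), 1:3),
               class = "emptyPopulationError")
})

test_that("a generated in-nucleus intensity ratio is recovered by the comparison", {
  runGroup <- function(seed, level) {
    cfg <- runConfig(seed = seed,
                     scene = list(n = 40L, phenotypeMix = c(uniform = 1)),
                     cell = list(dapiNucleusLevel = level))
    runPipeline(cfg)$quants
  }
  for (ratio in c(0.8, 1)) {
    a <- runGroup(61, 7500)
    b <- runGroup(62, 7500 * ratio)
    observed <- percentDifference(compareGroups(a, b))
    expect_lt(abs(observed - 100 * (1 - ratio)), 5)
  }
})
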