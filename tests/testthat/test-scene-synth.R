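test_that("noiseless blur-free render is constant on the cell and zero outside", {
  sp <- singleCellScene(psfSigma = 0, cameraOffset = 0, readNoiseSd = 0)
  rs <- renderScene(sp, noise = FALSE)
  gfp <- sceneImages(rs)$gfp
  gt <- groundTruth(rs)$cells[[1]]
  expect_true(all(gfp[gt$pixels] == 1500))
  expect_true(all(gfp[-gt$pixels] == 0))
})

test_that("rendering is bit-identical for identical SceneSpecs", {
  sp <- singleCellScene(seed = 7)
  a <- renderScene(sp)
  b <- renderScene(sp)
  for (ch in names(sceneImages(a))) {
    expect_identical(sceneImages(a)[[ch]], sceneImages(b)[[ch]])
  }
  expect_identical(groundTruth(a), groundTruth(b))
  other <- renderScene(singleCellScene(seed = 8))
  expect_false(identical(sceneImages(a)$gfp, sceneImages(other)$gfp))
})

test_that("rendered nucleus/cytoplasm contrast matches the spec in the noiseless limit", {
  # blur-free: exact; 1-px PSF: mean over the full masks is biased by
  # edge bleed, but pixels more than 3 sigma from any density boundary
  # recover the contrast to within 5%
  spExact <- singleCellScene(phenotype = "excluded", gfpContrast = 0.1,
                             psfSigma = 0, cameraOffset = 0, readNoiseSd = 0)
  rsExact <- renderScene(spExact, noise = FALSE)
  gt <- groundTruth(rsExact)$cells[[1]]
  g <- sceneImages(rsExact)$gfp
  expect_equal(mean(g[gt$nucleusPixels]) /
                 mean(g[setdiff(gt$pixels, gt$nucleusPixels)]),
               0.1, tolerance = 1e-10)

  sp1 <- singleCellScene(phenotype = "excluded", gfpContrast = 0.1,
                         psfSigma = 65, cameraOffset = 0, readNoiseSd = 0)
  rs1 <- renderScene(sp1, noise = FALSE)
  gt1 <- groundTruth(rs1)$cells[[1]]
  g1 <- sceneImages(rs1)$gfp
  dims <- dim(g1)
  nucCenter <- (gt1$axisP0 + gt1$axisP1) / 2
  rcNuc <- arrayInd(gt1$nucleusPixels, dims) - 1
  dNuc <- sqrt((rcNuc[, 1] - nucCenter[1])^2 + (rcNuc[, 2] - nucCenter[2])^2)
  nucleusRadius <- 0.8 * gt1$widthPx / 2
  inner <- gt1$nucleusPixels[dNuc <= nucleusRadius - 3]
  rcAll <- arrayInd(gt1$pixels, dims) - 1
  dAll <- sqrt((rcAll[, 1] - nucCenter[1])^2 + (rcAll[, 2] - nucCenter[2])^2)
  # cytoplasm pixels well away from the nucleus and the cell boundary
  perp <- abs((rcAll[, 1] - nucCenter[1]) * (gt1$axisP1[2] - gt1$axisP0[2]) -
                (rcAll[, 2] - nucCenter[2]) * (gt1$axisP1[1] - gt1$axisP0[1])) /
    gt1$lengthPx
  along <- abs(((rcAll[, 1] - nucCenter[1]) * (gt1$axisP1[1] - gt1$axisP0[1]) +
                  (rcAll[, 2] - nucCenter[2]) * (gt1$axisP1[2] - gt1$axisP0[2])) /
                 gt1$lengthPx)
  cyto <- gt1$pixels[dAll >= nucleusRadius + 3 &
                       perp <= gt1$widthPx / 2 - 3 &
                       along <= (gt1$lengthPx - gt1$widthPx) / 2]
  expect_gt(length(inner), 5)
  expect_gt(length(cyto), 20)
  expect_equal(mean(g1[inner]) / mean(g1[cyto]), 0.1, tolerance = 0.05)
})

test_that("shot noise is Poisson: per-pixel variance tracks the mean", {
  nRep <- 500
  shape <- c(64, 64)
  stack <- vapply(seq_len(nRep), function(i) {
    sp <- singleCellScene(imageShape = shape, cameraOffset = 0,
                          readNoiseSd = 0, length = 2, seed = i)
    sceneImages(renderScene(sp))$gfp
  }, matrix(0, shape[1], shape[2]))
  gt <- groundTruth(renderScene(
    singleCellScene(imageShape = shape, cameraOffset = 0, readNoiseSd = 0,
                    length = 2, seed = 1)))$cells[[1]]
  px <- gt$pixels
  mu <- apply(stack, c(1, 2), mean)[px]
  v <- apply(stack, c(1, 2), stats::var)[px]
  expect_equal(mean(v / mu), 1, tolerance = 0.1)
})

test_that("expected counts are linear in the photon scale", {
  mk <- function(scale) {
    sp <- singleCellScene(seed = 11)
    sp@optics@photonScale <- scale
    rs <- renderScene(sp)
    gt <- groundTruth(rs)$cells[[1]]
    mean(sceneImages(rs)$gfp[gt$pixels]) - sp@optics@cameraOffset
  }
  expect_equal(mk(2) / mk(1), 2, tolerance = 0.02)
})

test_that("uninfected cells carry no nucleus disk in any channel", {
  sp <- singleCellScene(infected = FALSE, psfSigma = 0, cameraOffset = 0,
                        readNoiseSd = 0)
  rs <- renderScene(sp, noise = FALSE)
  gt <- groundTruth(rs)$cells[[1]]
  expect_length(gt$nucleusPixels, 0)
  dapi <- sceneImages(rs)$dapi
  expect_true(all(dapi[gt$pixels] == 800))
})

test_that("overlapping or out-of-bounds cells are rejected", {
  twoCells <- SceneSpec(
    imageShape = c(120, 120),
    cells = list(CellSpec(center = c(60, 55)), CellSpec(center = c(60, 62))),
    seed = 1)
  expect_error(renderScene(twoCells), class = "overlapError")
  offEdge <- SceneSpec(imageShape = c(120, 120),
                       cells = list(CellSpec(center = c(5, 60))), seed = 1)
  expect_error(renderScene(offEdge), class = "geometryError")
})

test_that("makePopulation honors the phenotype mix and the seed", {
  scenes <- makePopulation(10, c(excluded = 1), seed = 3,
                           imageShape = c(400, 400), cellsPerScene = 10)
  labels <- unlist(lapply(scenes, function(s) {
    vapply(s@cells, function(cl) cl@phenotype, character(1))
  }))
  expect_identical(labels, rep("excluded", 10))

  mixA <- makePopulation(115, c(imported = 0.5, excluded = 0.5), seed = 9)
  mixB <- makePopulation(115, c(imported = 0.5, excluded = 0.5), seed = 9)
  labA <- unlist(lapply(mixA, function(s) {
    vapply(s@cells, function(cl) cl@phenotype, character(1))
  }))
  labB <- unlist(lapply(mixB, function(s) {
    vapply(s@cells, function(cl) cl@phenotype, character(1))
  }))
  expect_identical(labA, labB)
  expect_length(labA, 115)
  expect_setequal(unique(labA), c("imported", "excluded"))
  # realized counts are recoverable from the rendered ground truth
  gtLabels <- unlist(lapply(mixA, function(s) {
    vapply(groundTruth(renderScene(s, noise = FALSE))$cells,
           function(cl) cl$phenotype, character(1))
  }))
  expect_identical(sort(gtLabels), sort(labA))
})

test_that("invalid mixes and impossible packings fail loudly", {
  expect_error(makePopulation(5, c(imported = 0.6, excluded = 0.6), seed = 1),
               class = "configError")
  expect_error(makePopulation(5, c(bogus = 1), seed = 1),
               class = "configError")
  expect_error(
    makePopulation(20, c(uniform = 1), seed = 1,
                   imageShape = c(140, 140), cellsPerScene = 20),
    class = "overlapError")
})

test_that("uniform-phenotype cells classify as mixed/ambiguous in the noiseless limit", {
  scenes <- makePopulation(4, c(uniform = 1), seed = 5,
                           imageShape = c(400, 400), cellsPerScene = 4)
  rs <- renderScene(scenes[[1]], noise = FALSE)
  rois <- segmentCells(rs)
  expect_length(rois, 4)
  for (roi in rois) {
    prof <- normalizeProfile(extractProfile(sceneImages(rs)$gfp, longAxis(roi)))
    expect_identical(callLabel(classifyLocalization(prof)), "mixed_ambiguous")
  }
})
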