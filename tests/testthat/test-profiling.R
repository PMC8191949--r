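test_that("profile extraction reproduces closed-form bilinear values", {
  roi <- rectangleRoi(40, 40, rows = 18:22, cols = 5:35)
  flat <- extractProfile(matrix(100, 40, 40), roi, nPoints = 11)
  expect_equal(flat@valuesRaw, rep(100, 11))

  # 1-D ramp I(col) = col sampled along a horizontal axis from col 0 to 10
  ramp <- matrix(rep(0:39, each = 40), 40, 40)
  roi2 <- cellROI(2L, {
    m <- matrix(FALSE, 40, 40); m[19:21, 1:11] <- TRUE; m
  })
  roi2@axisP0 <- c(20, 0)
  roi2@axisP1 <- c(20, 10)
  roi2@lengthPx <- 10
  p <- extractProfile(ramp, roi2, nPoints = 11)
  expect_equal(p@valuesRaw, as.numeric(0:10))

  expect_error(extractProfile(ramp, roi2, nPoints = 2),
               class = "profileError")
  roi2@lengthPx <- 2
  roi2@axisP1 <- c(20, 2)
  expect_error(extractProfile(ramp, roi2), class = "profileError")
})

test_that("an imported cell peaks in the central fifth of the profile", {
  rs <- renderScene(singleCellScene(phenotype = "imported", gfpContrast = 3),
                    noise = FALSE)
  roi <- longAxis(segmentCells(rs)[[1]])
  p <- extractProfile(sceneImages(rs)$gfp, roi)
  peak <- p@positions[which.max(p@valuesRaw)]
  expect_true(peak >= 0.4 && peak <= 0.6)
})

test_that("normalization divides by the initial-end anchor", {
  p <- normalizeProfile(rawProfile(c(100, 150, 200, 150, 100)),
                        anchorFrac = 0.05)
  expect_equal(p@valuesNorm, c(1, 1.5, 2, 1.5, 1))
  expect_equal(p@anchor, 100)

  const <- normalizeProfile(rawProfile(rep(7, 21)))
  expect_equal(const@valuesNorm, rep(1, 21))

  expect_error(normalizeProfile(rawProfile(c(-5, -1, 3, 4, 5))),
               class = "normalizationError")
})

test_that("the anchor-window mean of a normalized profile is exactly 1", {
  set.seed(77)
  for (i in 1:20) {
    vals <- stats::runif(101, 50, 500)
    p <- normalizeProfile(rawProfile(vals), anchorFrac = 0.05)
    k <- max(1, ceiling(0.05 * 101))
    expect_equal(mean(p@valuesNorm[seq_len(k)]), 1, tolerance = 1e-12)
    expect_equal(p@valuesNorm * p@anchor, p@valuesRaw, tolerance = 1e-9)
  }
})

test_that("normalized profiles and calls are gain-invariant", {
  rs <- renderScene(singleCellScene(phenotype = "excluded",
                                    gfpContrast = 0.2, seed = 12))
  roi <- longAxis(segmentCells(rs)[[1]])
  gfp <- sceneImages(rs)$gfp
  for (g in c(0.25, 3.7)) {
    p1 <- normalizeProfile(extractProfile(gfp, roi))
    p2 <- normalizeProfile(extractProfile(gfp * g, roi))
    expect_equal(p1@valuesNorm, p2@valuesNorm, tolerance = 1e-12)
    expect_equal(callScore(classifyLocalization(p1)),
                 callScore(classifyLocalization(p2)), tolerance = 1e-12)
  }
})

test_that("classification separates imported, excluded and flat profiles", {
  flat <- normalizeProfile(rawProfile(rep(3, 101)))
  flatCall <- classifyLocalization(flat)
  expect_equal(callScore(flatCall), 1)
  expect_identical(callLabel(flatCall), "mixed_ambiguous")

  mkCall <- function(phenotype, contrast) {
    rs <- renderScene(singleCellScene(phenotype = phenotype,
                                      gfpContrast = contrast), noise = FALSE)
    roi <- longAxis(segmentCells(rs)[[1]])
    classifyLocalization(normalizeProfile(extractProfile(sceneImages(rs)$gfp,
                                                         roi)))
  }
  imp <- mkCall("imported", 3)
  expect_identical(callLabel(imp), "imported")
  expect_gt(callScore(imp), 1.2)
  exc <- mkCall("excluded", 0.2)
  expect_identical(callLabel(exc), "excluded")
  expect_lt(callScore(exc), 0.8)

  expect_error(classifyLocalization(rawProfile(rep(3, 101))),
               class = "classificationError")
})

test_that("the classification score is invariant to profile reversal", {
  set.seed(99)
  for (i in 1:10) {
    vals <- stats::runif(101, 10, 100) + seq(0, 50, length.out = 101)
    fwd <- classifyLocalization(normalizeProfile(rawProfile(vals)))
    rev <- classifyLocalization(normalizeProfile(rawProfile(rev(vals))))
    expect_equal(callScore(fwd), callScore(rev), tolerance = 1e-12)
    expect_identical(callLabel(fwd), callLabel(rev))
  }
})

test_that("orientation normalization reverses bright-second-half profiles only", {
  increasing <- normalizeProfile(rawProfile(seq(10, 110, length.out = 11)))
  out <- orientProfiles(list(increasing))[[1]]
  expect_equal(out@valuesRaw, rev(increasing@valuesRaw))
  expect_equal(mean(out@valuesNorm[1]), 1) # re-anchored after reversal

  symmetric <- normalizeProfile(rawProfile(c(1, 2, 3, 2, 1) * 10))
  expect_equal(orientProfiles(list(symmetric))[[1]]@valuesRaw,
               symmetric@valuesRaw)
  expect_equal(orientProfiles(list(increasing), enabled = FALSE)[[1]]@valuesRaw,
               increasing@valuesRaw)
})

test_that("ensemble averaging is the positionwise mean and sd", {
  single <- normalizeProfile(rawProfile(c(10, 30, 10)), anchorFrac = 0.05)
  e1 <- averageProfiles(list(single))
  expect_equal(e1@mean, single@valuesNorm)
  expect_equal(e1@sd, rep(0, 3))
  expect_identical(e1@n, 1L)

  up <- normalizeProfile(rawProfile(c(1, 2, 1)), anchorFrac = 0.05)
  down <- normalizeProfile(rawProfile(c(1, 0, 1)), anchorFrac = 0.05)
  e2 <- averageProfiles(list(up, down))
  expect_equal(e2@mean, c(1, 1, 1))
  expect_equal(e2@sd, c(0, stats::sd(c(2, 0)), 0))

  expect_error(averageProfiles(list(up, normalizeProfile(rawProfile(rep(1, 5))))),
               class = "ensembleError")
  expect_error(averageProfiles(list()), class = "ensembleError")
  expect_error(averageProfiles(list(rawProfile(c(1, 2, 1)))),
               class = "ensembleError")
})

test_that("population fractions tabulate calls and sum to one", {
  mkCalls <- function(labels) {
    lapply(seq_along(labels), function(i) {
      score <- switch(labels[i], imported = 2, excluded = 0.5,
                      mixed_ambiguous = 1)
      new("PhenotypeCall", cellId = i, score = score, call = labels[i],
          tHi = 1.2, tLo = 0.8)
    })
  }
  allExcluded <- populationFractions(mkCalls(rep("excluded", 177)))
  expect_equal(allExcluded$fractions[["excluded"]], 1)
  expect_identical(allExcluded$n, 177L)

  split <- populationFractions(mkCalls(c("imported", "excluded")))
  expect_equal(unname(split$fractions[c("imported", "excluded")]),
               c(0.5, 0.5))
  expect_equal(sum(split$fractions), 1)

  expect_error(populationFractions(list()), class = "emptyPopulationError")
})
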