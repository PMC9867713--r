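# Nuclei segmentation, marker calling, disrupted-region detection and
# apical-surface measurement, checked against planted ground truth.

# Match segmented centroids to truth cells: a hit is a segmented
# centroid whose nearest truth centroid is within `tolUm` and unclaimed.
matchCentroids <- function(seg, truth, pixelSize, tolUm) {
  claimed <- rep(FALSE, nrow(truth))
  hits <- 0L
  for (i in seq_len(nrow(seg))) {
    d <- sqrt((seg$row[i] - truth$row)^2 +
              (seg$col[i] - truth$col)^2) * pixelSize
    j <- which.min(d)
    if (d[j] <= tolUm && !claimed[j]) {
      claimed[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

test_that("well-separated planted nuclei are segmented one-to-one", {
  sim <- simulateMonolayer(fieldSize = c(300, 300), cellDiameterUm = 20,
                           disruptedFraction = 0, jitterFrac = 0.15,
                           noiseSd = 80, seed = 31)
  nuc <- segmentNuclei(sim$stack)
  truth <- sim$truth$cells
  hits <- matchCentroids(nucleusData(nuc), truth, 1, tolUm = 6)
  recall <- hits / nrow(truth)
  precision <- hits / nNuclei(nuc)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("a blank image yields zero nuclei", {
  stk <- miniStack(DAPI = matrix(100, 64, 64))
  nuc <- segmentNuclei(stk)
  expect_equal(nNuclei(nuc), 0L)
  expect_true(all(labelMap(nuc) == 0L))
})

test_that("two overlapping nuclei are split by the watershed", {
  nr <- 60; nc <- 60
  pr <- rep(1:nr - 1, times = nc); pc <- rep(1:nc - 1, each = nr)
  d1 <- sqrt((pr - 25)^2 + (pc - 27)^2)
  d2 <- sqrt((pr - 35)^2 + (pc - 33)^2)
  img <- matrix(200 + 20000 * ((d1 < 8) | (d2 < 8)), nr, nc)
  nuc <- segmentNuclei(miniStack(DAPI = img), sizeRangeUm2 = c(25, 1000))
  expect_equal(nNuclei(nuc), 2L)
})

test_that("missing or non-2D channels are rejected", {
  stk <- miniStack(DAPI = matrix(0, 16, 16))
  expect_error(segmentNuclei(stk, nucleiChannel = "Hoechst"), "not present")
  stk3 <- ImageStack(list(DAPI = array(0, c(8, 8, 3))), 1, zStep = 0.3)
  expect_error(segmentNuclei(stk3), "2D")
})

test_that("an all-zero marker channel yields zero positives", {
  sim <- simulateMonolayer(fieldSize = c(160, 160), disruptedFraction = 0,
                           seed = 13)
  stk <- ImageStack(list(DAPI = getChannel(sim$stack, "DAPI"),
                         BRACH = matrix(0, 160, 160)), 1)
  nuc <- segmentNuclei(stk)
  calls <- callNuclearMarker(stk, nuc, "BRACH")
  expect_equal(nPositive(calls), 0L)
  expect_equal(nTotal(calls), nNuclei(nuc))
})

test_that("marker calls recover the planted positive set", {
  # uniform planted positivity far from any disruption; strong signal
  sim <- simulateMonolayer(fieldSize = c(300, 300), cellDiameterUm = 18,
                           disruptedFraction = 0, jitterFrac = 0.15,
                           markerProbByRing = rep(0.3, 4), noiseSd = 60,
                           seed = 17)
  nuc <- truthNuclei(sim)
  calls <- callNuclearMarker(sim$stack, nuc, "BRACH")
  truthPos <- sim$truth$cells$positive
  expect_identical(unname(positiveCalls(calls)), truthPos)
  expect_equal(nPositive(calls), sum(truthPos))
})

test_that("marker threshold equals the exhaustive Otsu oracle on the processed image", {
  sim <- simulateMonolayer(fieldSize = c(200, 200), disruptedFraction = 0,
                           markerProbByRing = rep(0.5, 4), noiseSd = 60,
                           seed = 23)
  nuc <- truthNuclei(sim)
  calls <- callNuclearMarker(sim$stack, nuc, "BRACH",
                             backgroundRadiusUm = 50, topHatRadiusUm = 12)
  proc <- subtractBackground(getChannel(sim$stack, "BRACH"), 50, 1)
  proc <- EBImage::whiteTopHat(proc / 65535,
                               EBImage::makeBrush(25, "disc")) * 65535
  expect_lte(abs(thresholdUsed(calls) - otsuOracle(as.numeric(proc))), 1)
})

test_that("a perfect junction network yields zero disrupted area", {
  sim <- simulateMonolayer(fieldSize = c(256, 256), disruptedFraction = 0,
                           seed = 41)
  det <- detectDisruptedRegions(sim$stack)
  expect_equal(areaFraction(det), 0)
  expect_identical(maskProvenance(det), "auto")
})

test_that("an empty junction channel is fully disrupted", {
  stk <- miniStack(DAPI = matrix(100, 96, 96), ZO1 = matrix(0, 96, 96))
  det <- detectDisruptedRegions(stk)
  expect_equal(areaFraction(det), 100)
})

test_that("planted disruption is detected with matching area and location", {
  sim <- simulateMonolayer(fieldSize = c(400, 400), disruptedFraction = 0.4,
                           seed = 7)
  det <- detectDisruptedRegions(sim$stack)
  truthM <- regionMask(sim$truth$mask)
  detM <- regionMask(det)
  iou <- sum(detM & truthM) / sum(detM | truthM)
  expect_gte(iou, 0.7)
  expect_lt(abs(areaFraction(det) - areaFraction(sim$truth$mask)), 5)
})

test_that("detected fraction is monotone in the planted fraction", {
  det <- vapply(c(0.15, 0.4, 0.6), function(f) {
    sim <- simulateMonolayer(fieldSize = c(300, 300), disruptedFraction = f,
                             seed = 19)
    areaFraction(detectDisruptedRegions(sim$stack))
  }, numeric(1))
  expect_true(all(diff(det) > 0))
})

test_that("manual masks round-trip with exact area fractions", {
  stk <- miniStack(ZO1 = matrix(1000, 100, 100))
  m <- matrix(FALSE, 100, 100); m[sample(10000, 3917)] <- TRUE
  p <- file.path(tempdir(), "mask.png")
  writeRegionMask(RegionMask(m, 1), p)
  rm <- loadManualMask(p, stk)
  expect_identical(maskProvenance(rm), "manual")
  expect_equal(areaFraction(rm), 39.17)
  expect_identical(regionMask(rm), m)
  # empty and full masks
  writeRegionMask(RegionMask(matrix(FALSE, 100, 100), 1), p)
  expect_equal(areaFraction(loadManualMask(p, stk)), 0)
  writeRegionMask(RegionMask(matrix(TRUE, 100, 100), 1), p)
  expect_equal(areaFraction(loadManualMask(p, stk)), 100)
  # shape mismatch
  small <- miniStack(ZO1 = matrix(0, 50, 50))
  expect_error(loadManualMask(p, small), "shape")
})

test_that("a single enclosed square cell measures its exact interior area", {
  img <- matrix(0, 40, 40)
  img[14:25, 14:25] <- 30000   # junction square ring ...
  img[15:24, 15:24] <- 0       # ... enclosing a 10 x 10 interior
  stk <- ImageStack(list(ZO1 = img), pixelSize = 0.5)
  ap <- measureApicalSurfaces(stk, shareJunction = FALSE, minAreaUm2 = 1)
  expect_equal(nrow(ap), 1L)
  expect_equal(ap$area_um2, 100 * 0.5^2)   # 25 um^2
})

test_that("apical surfaces recover the generating polygon areas", {
  sim <- simulateMonolayer(fieldSize = c(300, 300), pixelSizeUm = 0.5,
                           cellDiameterUm = 18, disruptedFraction = 0,
                           noiseSd = 80, seed = 5)
  ap <- measureApicalSurfaces(sim$stack)
  truth <- sim$truth$cells
  lm <- sim$truth$labelMap
  # look up the truth cell under each measured centroid
  lab <- lm[cbind(round(ap$row) + 1L, round(ap$col) + 1L)]
  rel <- abs(ap$area_um2 - truth$area_um2[lab]) / truth$area_um2[lab]
  expect_gte(nrow(ap), 20)
  expect_lt(stats::median(rel), 0.05)
  expect_lt(mean(rel > 0.10), 0.05)   # isolated boundary ties only
})

test_that("halving the cell diameter quarters the mean apical surface", {
  # diameters dividing the 150 um field so the lattice pitch is exact
  a <- simulateMonolayer(fieldSize = c(300, 300), pixelSizeUm = 0.5,
                         cellDiameterUm = 15, disruptedFraction = 0,
                         noiseSd = 60, seed = 9)
  b <- simulateMonolayer(fieldSize = c(300, 300), pixelSizeUm = 0.5,
                         cellDiameterUm = 7.5, disruptedFraction = 0,
                         noiseSd = 60, seed = 9)
  ma <- mean(measureApicalSurfaces(a$stack)$area_um2)
  mb <- mean(measureApicalSurfaces(b$stack)$area_um2)
  expect_lt(abs(mb / ma - 0.25), 0.25 * 0.10)
})

test_that("an empty junction channel cannot delimit cells", {
  stk <- miniStack(ZO1 = matrix(0, 32, 32))
  expect_error(measureApicalSurfaces(stk), "empty")
})
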