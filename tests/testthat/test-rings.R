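# Distance-ring construction and the positivity-versus-distance
# statistic, checked against analytic geometry, a brute-force distance
# oracle, and closed-form least squares.

test_that("ring pixel counts around a disk match analytic annulus areas", {
  m <- diskMask(220, 220, r = 50)
  rb <- makeRingMasks(RegionMask(m, pixelSize = 1))
  counts <- tabulate(ringIndexMap(rb), nbins = 5)
  expect_equal(counts[1], sum(m))
  # ring [0,30): pixels with 0 < d <= ~30 -> annulus pi*(80^2 - 50^2)
  expect_lt(abs(counts[2] - pi * (80^2 - 50^2)) / (pi * (80^2 - 50^2)),
            0.02)
  expect_lt(abs(counts[3] - pi * (110^2 - 80^2)) / (pi * (110^2 - 80^2)),
            0.02)
})

test_that("ring assignment agrees with the brute-force distance oracle", {
  set.seed(5)
  for (rep in 1:4) {
    m <- blobMask(96, 96, nDisks = 5)
    rb <- makeRingMasks(RegionMask(m, pixelSize = 2))  # 2 um/px
    d <- bruteDistance(m) * 2
    expected <- ifelse(m, 1L, 2L + findInterval(d, c(30, 60, 90)))
    expect_identical(ringIndexMap(rb), matrix(as.integer(expected), 96, 96))
  }
})

test_that("the five ring masks are disjoint and tile the image", {
  set.seed(8)
  for (rep in 1:3) {
    m <- blobMask(80, 120, nDisks = 4)
    rb <- makeRingMasks(RegionMask(m, pixelSize = 1.5))
    rms <- ringMasks(rb)
    overlapSum <- Reduce(`+`, lapply(rms, function(x) x * 1L))
    expect_true(all(overlapSum == 1L))   # every pixel in exactly one ring
  }
})

test_that("degenerate masks follow the ring contracts", {
  expect_error(makeRingMasks(RegionMask(matrix(FALSE, 10, 10), 1)),
               "empty")
  expect_warning(rb <- makeRingMasks(RegionMask(matrix(TRUE, 10, 10), 1)),
                 "whole image")
  expect_true(all(ringIndexMap(rb) == 1L))
  expect_error(makeRingMasks(RegionMask(diskMask(20, 20, 5), 1),
                             edgesUm = c(10, 30)), "start at 0")
})

test_that("positive fractions per ring follow the contracts", {
  sim <- simulateMonolayer(fieldSize = c(300, 300), disruptedFraction = 0.3,
                           markerProbByRing = rep(1, 4), seed = 6)
  nuc <- truthNuclei(sim)
  rings <- makeRingMasks(sim$truth$mask)
  prof <- binPositiveFractions(nuc, truthCalls(sim), rings)
  expect_true(all(prof$fraction_percent[prof$n_cells > 0] == 100))
  expect_equal(sum(prof$n_cells), nNuclei(nuc))
  # empty far ring on a small field: NA, not 0
  m <- matrix(FALSE, 60, 60); m[25:35, 25:35] <- TRUE  # everything < 90 um
  rb2 <- makeRingMasks(RegionMask(m, pixelSize = 1))
  lm <- matrix(0L, 60, 60); lm[10, 10] <- 1L; lm[50, 50] <- 2L
  nuc2 <- NucleusTable(lm, data.frame(label = 1:2, row = c(9, 49),
                                      col = c(9, 49), area_um2 = c(1, 1)), 1)
  calls2 <- MarkerCalls("X", c(`1` = TRUE, `2` = FALSE), 0)
  pr2 <- binPositiveFractions(nuc2, calls2, rb2)
  expect_true(is.na(pr2$fraction_percent[pr2$bin == ">+90"]))
  expect_equal(pr2$n_cells[pr2$bin == ">+90"], 0L)
  # label mismatch
  expect_error(binPositiveFractions(nuc2, MarkerCalls("X", c(`7` = TRUE), 0),
                                    rb2), "labels")
})

test_that("planted ring probabilities are recovered within sampling error", {
  sim <- simulateMonolayer(fieldSize = c(420, 420), pixelSizeUm = 1.5,
                           cellDiameterUm = 14, disruptedFraction = 0.25,
                           nPatches = 2,
                           markerProbByRing = c(0.9, 0.7, 0.5, 0.3),
                           seed = 10)
  prof <- binPositiveFractions(truthNuclei(sim), truthCalls(sim),
                               makeRingMasks(sim$truth$mask))
  planted <- c(0.9, 0.9, 0.7, 0.5, 0.3)   # inside shares the first ring
  for (k in seq_len(5)) {
    n <- prof$n_cells[k]
    if (n < 30) next
    se <- sqrt(planted[k] * (1 - planted[k]) / n)
    expect_lt(abs(prof$fraction_percent[k] / 100 - planted[k]), 3.5 * se)
  }
})

test_that("slope fitting matches closed-form least squares", {
  pr <- data.frame(bin = c("0", "+30", "+60", "+90", ">+90"),
                   bin_index = 0:4, n_cells = rep(100L, 5),
                   n_positive = c(100, 88, 76, 64, 52),
                   fraction_percent = c(100, 88, 76, 64, 52))
  fit <- fitDistanceSlope(pr)
  expect_equal(fit$m, -12)
  expect_equal(fit$intercept, 100)
  expect_equal(fit$r_squared, 1)
  # flat profile: slope 0, exact fit
  pr$fraction_percent <- rep(55, 5)
  flat <- fitDistanceSlope(pr)
  expect_equal(flat$m, 0)
  expect_equal(flat$r_squared, 1)
  # NA bins are dropped and the fit matches the oracle on the rest
  pr$fraction_percent <- c(90, 70, NA, 40, 20)
  fit2 <- fitDistanceSlope(pr)
  oracle <- olsOracle(c(0, 1, 3, 4), c(90, 70, 40, 20))
  expect_equal(fit2$m, unname(oracle["slope"]))
  expect_equal(fit2$n_bins, 4L)
  # fewer than two usable bins
  pr$fraction_percent <- c(50, NA, NA, NA, NA)
  expect_error(fitDistanceSlope(pr), "at least two")
})

test_that("bin centers in micrometres are the documented abscissa", {
  pr <- data.frame(bin = c("0", "+30", "+60", "+90", ">+90"),
                   bin_index = 0:4, n_cells = rep(10L, 5),
                   n_positive = rep(5L, 5),
                   fraction_percent = c(100, 85, 55, 25, 10))
  fit <- fitDistanceSlope(pr, xConvention = "bin_center_um")
  oracle <- olsOracle(c(0, 15, 45, 75, 105), pr$fraction_percent)
  expect_equal(fit$m, unname(oracle["slope"]))
  expect_identical(fit$x_convention, "bin_center_um")
})

test_that("area-fraction time courses report exact complements", {
  masks <- list(
    list(time = 0, mask = RegionMask(diskMask(50, 50, 20), 1)),
    list(time = 9, mask = RegionMask(diskMask(50, 50, 10), 1)),
    list(time = 18, mask = RegionMask(matrix(FALSE, 50, 50), 1)))
  tc <- areaFractionTimecourse(masks)
  expect_equal(tc$organized_percent + tc$disrupted_percent, rep(100, 3))
  expect_equal(tc$disrupted_percent,
               vapply(masks, function(m) areaFraction(m$mask), numeric(1)))
  one <- areaFractionTimecourse(masks[1])
  expect_equal(nrow(one), 1L)
  expect_error(areaFractionTimecourse(masks[c(1, 1)]), "duplicate")
  expect_error(areaFractionTimecourse(masks[c(2, 1)]), "increasing")
})

test_that("z-profile peak distances locate planted axial peaks", {
  nz <- 21; dz <- 0.3
  z <- (seq_len(nz) - 1) * dz
  mkStack <- function(muA, muB) {
    a <- array(0, c(8, 8, nz)); b <- array(0, c(8, 8, nz))
    for (k in seq_len(nz)) {
      a[, , k] <- 1000 * exp(-(z[k] - muA)^2 / (2 * 0.5^2))
      b[, , k] <- 1000 * exp(-(z[k] - muB)^2 / (2 * 0.5^2))
    }
    ImageStack(list(A = a, B = b), pixelSize = 0.1, zStep = dz)
  }
  # identical channels: zero distance
  same <- zProfilePeakDistance(mkStack(3, 3), "A", "A")
  expect_equal(same$peak_distance_nm, 0)
  expect_false(same$edge_peak_flag)
  # planted 1.2 um separation on a 0.3 um grid, within half a z-step
  apart <- zProfilePeakDistance(mkStack(2.2, 3.4), "A", "B")
  expect_lt(abs(apart$peak_distance_nm - 1200), 150)
  # monotone profile peaks at the boundary slice
  mono <- mkStack(10, 3)   # A's peak beyond the last slice
  res <- zProfilePeakDistance(mono, "A", "B")
  expect_true(res$edge_peak_flag)
  # 2D stacks are rejected
  flat <- miniStack(A = matrix(0, 8, 8), B = matrix(0, 8, 8))
  expect_error(zProfilePeakDistance(flat, "A", "B"), "3D")
})
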