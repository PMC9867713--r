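# The generators must deliver exactly the conditions they promise:
# planted area fractions, seeded determinism, geometric scaling and
# noise-free truth profiles.

test_that("planted disrupted fraction is recovered from the truth mask", {
  for (f in c(0.05, 0.2, 0.4, 0.6, 0.8)) {
    sim <- simulateMonolayer(fieldSize = c(200, 200), disruptedFraction = f,
                             seed = 7)
    expect_lt(abs(areaFraction(sim$truth$mask) / 100 - f), 0.02)
  }
})

test_that("zero disrupted fraction gives an empty mask and all cells in the far ring", {
  sim <- simulateMonolayer(fieldSize = c(160, 160), disruptedFraction = 0,
                           seed = 3)
  expect_false(any(regionMask(sim$truth$mask)))
  expect_true(all(sim$truth$cells$ring_index == 3L))
  expect_true(all(sim$truth$cells$distance_class == ">+90"))
})

test_that("identical spec and seed reproduce bit-identical images and truth", {
  a <- simulateMonolayer(fieldSize = c(128, 128), seed = 11)
  b <- simulateMonolayer(fieldSize = c(128, 128), seed = 11)
  for (ch in channelNames(a$stack))
    expect_identical(getChannel(a$stack, ch), getChannel(b$stack, ch))
  expect_identical(regionMask(a$truth$mask), regionMask(b$truth$mask))
  expect_identical(a$truth$cells, b$truth$cells)
  c2 <- simulateMonolayer(fieldSize = c(128, 128), seed = 12)
  expect_false(identical(getChannel(a$stack, "DAPI"),
                         getChannel(c2$stack, "DAPI")))
})

test_that("generator leaves the caller's RNG state untouched", {
  set.seed(99); before <- .Random.seed
  invisible(simulateMonolayer(fieldSize = c(64, 64), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("mean truth cell area scales as the squared cell diameter", {
  a <- simulateMonolayer(fieldSize = c(360, 360), cellDiameterUm = 12,
                         disruptedFraction = 0, seed = 4)
  b <- simulateMonolayer(fieldSize = c(360, 360), cellDiameterUm = 24,
                         disruptedFraction = 0, seed = 4)
  ratio <- mean(b$truth$cells$area_um2) / mean(a$truth$cells$area_um2)
  expect_lt(abs(ratio / 4 - 1), 0.10)
})

test_that("infeasible packings are rejected with an explicit error", {
  expect_error(simulateMonolayer(fieldSize = c(32, 32), cellDiameterUm = 30),
               "packing")
  expect_error(simulateMonolayer(cellDiameterUm = 2, pixelSizeUm = 1),
               "packing")
})

test_that("time course hits one-minus-organized at every point, monotonically", {
  tc <- simulateTimecourse(c(`0` = 0.1, `9` = 0.5, `18` = 0.9),
                           fieldSize = c(200, 200), seed = 21)
  fr <- vapply(tc, function(e) areaFraction(e$truth$mask) / 100, numeric(1))
  expect_equal(fr, c(0.9, 0.5, 0.1), tolerance = 0.02)
  expect_true(all(diff(fr) < 0))
  flat <- simulateTimecourse(c(`0` = 1, `6` = 1), fieldSize = c(96, 96),
                             seed = 2)
  expect_true(all(vapply(flat, function(e)
    !any(regionMask(e$truth$mask)), logical(1))))
  expect_error(simulateTimecourse(c(`3` = 0.5, `1` = 0.2)), "increasing")
  expect_error(simulateTimecourse(c(`1` = 0.5, `1` = 0.2)), "duplicate")
  expect_error(simulateTimecourse(c(`1` = 1.5)), "\\[0, 1\\]")
})

test_that("colony disks have the stated diameter and noise-free truth", {
  col <- simulateColonies(nColonies = 2, diameterUm = 700, pixelSizeUm = 1,
                          noiseSd = 0, seed = 5)
  dapi <- getChannel(col$stacks[[1]], "DAPI")
  # disk diameter from the widest row of the foreground
  widths <- apply(dapi > 0, 1, sum)
  expect_lt(abs(max(widths) - 700), 2)
  # annular domain: zero inside the inner radius, planted value outside
  tr <- col$truth$profiles
  br <- tr[tr$channel == "BRACH", ]
  expect_true(all(br$intensity[br$r_frac < 0.75] == 0))
  expect_true(all(br$intensity[br$r_frac >= 0.75] == 15000))
})

test_that("noisy colonies differ from one another but share one truth", {
  col <- simulateColonies(nColonies = 3, pixelSizeUm = 4, noiseSd = 400,
                          seed = 8)
  s1 <- getChannel(col$stacks[[1]], "SOX2")
  s2 <- getChannel(col$stacks[[2]], "SOX2")
  expect_false(identical(s1, s2))
  again <- simulateColonies(nColonies = 3, pixelSizeUm = 4, noiseSd = 400,
                            seed = 8)
  expect_identical(col$truth$profiles, again$truth$profiles)
  expect_identical(s1, getChannel(again$stacks[[1]], "SOX2"))
})

test_that("overlapping same-channel fate domains are rejected", {
  bad <- data.frame(channel = c("BRACH", "BRACH"), inner = c(0.5, 0.6),
                    outer = c(0.8, 1.0), intensity = c(1, 1))
  expect_error(simulateColonies(fateDomains = bad), "overlap")
  bad2 <- data.frame(channel = "SOX2", inner = 0.7, outer = 0.6,
                     intensity = 1)
  expect_error(simulateColonies(fateDomains = bad2), "inner < outer")
})
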