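test_that("slab boundaries recover synthetic leaflet planes", {
  g <- synthMembranePatch(nInner = 100L, nOuter = 100L, area = 80,
                          leafletSep = 4, zJitter = 0, seed = 51)
  sb <- slabBoundaries(g$frame, g$system)
  mid <- groundTruth(g)$midplane
  expect_equal(sb$zLow, mid - 2, tolerance = 1e-9)
  expect_equal(sb$zHigh, mid + 2, tolerance = 1e-9)
})

test_that("crown-deformed boundaries are leaflet means with spread", {
  g <- synthMembranePatch(nInner = 300L, nOuter = 300L, area = 400,
                          crownHeight = 1.5, ringRadius = 8,
                          zJitter = 0, seed = 52)
  sb <- slabBoundaries(g$frame, g$system)
  expect_gt(sb$sdHigh, 0)  # deformation shows up as spread
  expect_gt(sb$zHigh, groundTruth(g)$midplane + 2)  # lifted mean
})

test_that("boundary definition refuses an empty leaflet", {
  g <- synthMembranePatch(nInner = 20L, nOuter = 20L, area = 30,
                          seed = 53)
  sys <- g$system
  res <- residues(sys)
  leaflets(sys) <- rep("outer", nrow(res))
  expect_error(slabBoundaries(g$frame, sys), "empty leaflet")
})

test_that("path types produce their planted event counts", {
  plan <- data.frame(
    species = c(rep("NA", 3), rep("CL", 2), rep("NA", 4), "CL"),
    type = c(rep("full_up", 3), rep("full_down", 2),
             rep("rebound", 4), "pbc_wrapped_cross"))
  p <- synthIonPaths(plan, slab = c(4, 8), nFrames = 200L, Lz = 12,
                     seed = 54)
  pe <- permeationEvents(p$z, list(zLow = 4, zHigh = 8), Lz = 12,
                         species = plan$species)
  expect_equal(sum(pe$events$direction == "up"), 4L)
  expect_equal(sum(pe$events$direction == "down"), 2L)
  ## per-ion agreement with both the planted truth and the brute-force
  ## state-sequence oracle
  for (i in seq_len(nrow(plan))) {
    evUp <- sum(pe$events$ion == i & pe$events$direction == "up")
    evDown <- sum(pe$events$ion == i & pe$events$direction == "down")
    oracle <- bruteCrossings(p$z[i, ], 4, 8, 12)
    expect_equal(evUp, unname(oracle["up"]))
    expect_equal(evDown, unname(oracle["down"]))
    expect_equal(evUp, p$truth$up[i])
    expect_equal(evDown, p$truth$down[i])
  }
})

test_that("boundary dithering yields no events despite many crossings", {
  p <- synthIonPaths(data.frame(species = "NA",
                                type = "boundary_dither"),
                     slab = c(4, 8), nFrames = 400L, Lz = 12,
                     seed = 55)
  pe <- permeationEvents(p$z, list(zLow = 4, zHigh = 8), Lz = 12)
  expect_equal(nrow(pe$events), 0L)
  ## the path does cross the lower boundary many times
  crossings <- sum(diff(p$z[1, ] > 4) != 0)
  expect_gt(crossings, 20)
})

test_that("periodic wrapping is unwrapped to a single event", {
  p <- synthIonPaths(data.frame(species = "NA",
                                type = "pbc_wrapped_cross"),
                     slab = c(4, 8), nFrames = 200L, Lz = 12,
                     seed = 56)
  ## the wrapped coordinate jumps across the box edge at least once
  expect_true(any(abs(diff(p$z[1, ])) > 6))
  pe <- permeationEvents(p$z, list(zLow = 4, zHigh = 8), Lz = 12)
  expect_equal(nrow(pe$events), 1L)
  expect_equal(pe$events$direction, "up")
})

test_that("event counts are invariant to uniform z-translation", {
  plan <- data.frame(species = c("NA", "CL"),
                     type = c("full_up", "full_down"))
  p <- synthIonPaths(plan, slab = c(4, 8), nFrames = 150L, Lz = 12,
                     seed = 57)
  pe1 <- permeationEvents(p$z, list(zLow = 4, zHigh = 8), Lz = 12)
  shift <- 1.3
  pe2 <- permeationEvents((p$z + shift) %% 12,
                          list(zLow = 4 + shift, zHigh = 8 + shift),
                          Lz = 12)
  expect_equal(pe1$events$direction, pe2$events$direction)
})

test_that("non-finite coordinates are reported with the frame", {
  z <- matrix(seq(1, 10, length.out = 20), nrow = 1)
  z[1, 7] <- NA
  expect_error(permeationEvents(z, list(zLow = 4, zHigh = 8), Lz = 12),
               "frame 6")
})

test_that("cumulative counts mirror the event table", {
  plan <- data.frame(species = c("NA", "NA", "CL"),
                     type = c("full_up", "full_up", "full_down"))
  p <- synthIonPaths(plan, slab = c(4, 8), nFrames = 100L, Lz = 12,
                     seed = 58)
  pe <- permeationEvents(p$z, list(zLow = 4, zHigh = 8), Lz = 12,
                         species = plan$species)
  lastRow <- pe$cumulative[nrow(pe$cumulative), ]
  expect_equal(lastRow$NA_up, 2)
  expect_equal(lastRow$CL_down, 1)
})

test_that("a filled water column is continuous, a gap is found", {
  w <- synthWaterColumn(c(4, 8), center = c(5, 5), radius = 1,
                        binDz = 0.3, seed = 59)
  wc <- waterContinuity(w$frame, w$system, axisCenter = c(5, 5),
                        cylinderRadius = 1, zRange = c(4, 8))
  expect_true(wc$continuous)
  wg <- synthWaterColumn(c(4, 8), gapBins = 5L, binDz = 0.3, seed = 60)
  wcg <- waterContinuity(wg$frame, wg$system, axisCenter = c(5, 5),
                         cylinderRadius = 1, zRange = c(4, 8))
  expect_false(wcg$continuous)
  expect_true(5L %in% wcg$gaps)
})

test_that("a zero-radius cylinder is degenerate and warned about", {
  w <- synthWaterColumn(c(4, 8), seed = 61)
  expect_warning(
    wc <- waterContinuity(w$frame, w$system, axisCenter = c(5, 5),
                          cylinderRadius = 0, zRange = c(4, 8)),
    "never")
  expect_false(wc$continuous)
})
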