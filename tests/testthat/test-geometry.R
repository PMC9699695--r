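test_that("planted pore radii are recovered within one grid cell", {
  for (R in c(2, 5, 10)) {
    area <- max(150, 4 * (R + 5)^2)
    nl <- floor((area - pi * R^2) / 0.7)
    g <- synthMembranePatch(nInner = nl, nOuter = nl, area = area,
                            poreRadius = R, seed = 70 + R)
    pr <- poreRadius(g$frame, g$system, grid = 0.5)
    expect_true(pr$hasPore)
    expect_equal(pr$radius, R, tolerance = 0.5 / R)
  }
})

test_that("pore radius is monotone in the planted radius", {
  radii <- vapply(c(2, 4, 6, 8), function(R) {
    nl <- floor((450 - pi * R^2) / 0.7)
    g <- synthMembranePatch(nInner = nl, nOuter = nl, area = 450,
                            poreRadius = R, seed = 75)
    poreRadius(g$frame, g$system)$radius
  }, numeric(1))
  expect_true(all(diff(radii) > 0))
})

test_that("an intact membrane reports no pore", {
  g <- synthMembranePatch(seed = 76)
  pr <- poreRadius(g$frame, g$system)
  expect_false(pr$hasPore)
  expect_equal(pr$diameter, 0)
})

test_that("too coarse a raster is rejected", {
  g <- synthMembranePatch(seed = 77)
  expect_error(poreRadius(g$frame, g$system, grid = 3), "coarser")
})

test_that("planted crown height is recovered within 0.1 nm", {
  g <- synthMembranePatch(nInner = 1500L, nOuter = 1500L, area = 1225,
                          crownHeight = 2, ringRadius = 15, seed = 78)
  dp <- deformationProfile(g$frame, g$system)
  expect_equal(dp$crownHeight, 2, tolerance = 0.05)
})

test_that("a flat patch has near-zero crown height", {
  g <- synthMembranePatch(nInner = 300L, nOuter = 300L, area = 400,
                          seed = 79)
  dp <- deformationProfile(g$frame, g$system)
  expect_lt(abs(dp$crownHeight), 0.15)
})

test_that("crown height is invariant under z-translation", {
  g <- synthMembranePatch(nInner = 500L, nOuter = 500L, area = 450,
                          crownHeight = 1.2, ringRadius = 8, seed = 80)
  dp1 <- deformationProfile(g$frame, g$system)
  shifted <- new("Frame", time = 0,
                 coords = coords(g$frame) +
                   rep(c(0, 0, 2), each = nAtoms(g$frame)),
                 box = boxDims(g$frame) + c(0, 0, 4))
  dp2 <- deformationProfile(shifted, g$system)
  expect_equal(dp1$crownHeight, dp2$crownHeight, tolerance = 1e-9)
})

test_that("hairpin tilt handles the degenerate directions", {
  ## vector along z reads 90 degrees, in-plane reads 0
  up <- synthRing(4L, hairpinTilt = 90, domainSpread = 0, seed = 81)
  expect_equal(hairpinTilt(up$frame, up$system)$tilt, rep(90, 4),
               tolerance = 1e-9)
  flat <- synthRing(4L, hairpinTilt = 0, domainSpread = 0, seed = 82)
  expect_equal(hairpinTilt(flat$frame, flat$system)$tilt, rep(0, 4),
               tolerance = 1e-9)
})

test_that("planted 55-degree hairpins are recovered within 0.5 degrees", {
  r <- synthRing(16L, arcFraction = 16 / 33, hairpinTilt = 55,
                 seed = 83)
  ht <- hairpinTilt(r$frame, r$system)
  expect_equal(ht$tilt, rep(55, 16), tolerance = 0.5 / 55)
})

test_that("geometry observables are invariant under xy-translation and
          z-rotation", {
  r <- synthRing(12L, hairpinTilt = 40, seed = 84)
  rot <- pi / 5
  pos <- coords(r$frame)
  ctr <- c(boxDims(r$frame)[1:2] / 2, 0)
  rel <- sweep(pos, 2, ctr)
  rotated <- cbind(rel[, 1] * cos(rot) - rel[, 2] * sin(rot),
                   rel[, 1] * sin(rot) + rel[, 2] * cos(rot),
                   rel[, 3])
  moved <- sweep(rotated, 2, ctr + c(1.0, -0.7, 0), `+`)
  frame2 <- new("Frame", time = 0, coords = moved,
                box = boxDims(r$frame) + c(4, 4, 0))
  t1 <- hairpinTilt(r$frame, r$system)$tilt
  t2 <- hairpinTilt(frame2, r$system)$tilt
  expect_equal(t1, t2, tolerance = 1e-9)
  c1 <- ringCircularity(r$frame, r$system)$fit
  c2 <- ringCircularity(frame2, r$system)$fit
  expect_equal(c1$radius, c2$radius, tolerance = 1e-9)
  expect_equal(c1$rms, c2$rms, tolerance = 1e-9)
})

test_that("exact circles fit with zero residual", {
  theta <- seq(0, 2 * pi, length.out = 20)[-20]
  xy <- cbind(3 + 7 * cos(theta), -2 + 7 * sin(theta))
  fit <- circleFit(xy)
  expect_equal(fit$center, c(3, -2), tolerance = 1e-9)
  expect_equal(fit$radius, 7, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  expect_error(circleFit(xy[1:2, ]), "at least 3")
})

test_that("a planted crack is reported at its planted time", {
  cs <- synthCrackSeries(16L, crackInterface = 8L, crackFrame = 890L,
                         nFrames = 1200L, seed = 85)
  cr <- detectCracks(cs, threshold = 5, persistence = 50L, dt = 0.001)
  expect_equal(nrow(cr), 1L)
  expect_equal(cr$interface, "8-9")
  expect_equal(cr$crackTime, 0.89, tolerance = 1e-9)
})

test_that("an uncracked arc yields an empty crack report", {
  cs <- synthCrackSeries(16L, nFrames = 500L, seed = 86)
  expect_equal(nrow(detectCracks(cs)), 0L)
})

test_that("a zero threshold can never crack", {
  cs <- synthCrackSeries(8L, crackInterface = 4L, crackFrame = 10L,
                         nFrames = 300L, seed = 87)
  expect_equal(nrow(detectCracks(cs, threshold = 0)), 0L)
})

test_that("inter-subunit contact counts drop at a geometric split", {
  r <- synthRing(8L, ringRadius = 3.2, domainSpread = 0.5,
                 domainBeads = 40L, seed = 88)
  counts <- subunitContactCounts(r$frame, r$system, cutoff = 1.2,
                                 closed = TRUE)
  expect_true(all(counts > 0))
  ## pull subunit 5 radially outward: interfaces 4-5 and 5-6 break
  sys <- r$system
  res <- residues(sys)
  at <- atoms(sys)
  rows <- which(at$residueKey %in% res$key[res$subunit %in% 5L])
  pos <- coords(r$frame)
  gt <- groundTruth(r)
  dir <- colMeans(pos[rows, 1:2]) - gt$center
  dir <- dir / sqrt(sum(dir^2))
  pos[rows, 1:2] <- sweep(pos[rows, 1:2], 2, 5 * dir, `+`)
  broken <- new("Frame", time = 0, coords = pos, box = boxDims(r$frame))
  counts2 <- subunitContactCounts(broken, sys, cutoff = 1.2,
                                  closed = TRUE)
  expect_equal(unname(counts2[c("4-5", "5-6")]), c(0L, 0L))
  expect_true(all(counts2[setdiff(names(counts2),
                                  c("4-5", "5-6"))] > 0))
})

test_that("membrane thinning maps a planted thin annulus", {
  g <- synthMembranePatch(nInner = 1200L, nOuter = 1200L, area = 900,
                          thinning = list(rIn = 6, rOut = 10,
                                          factor = 0.7),
                          zJitter = 0.02, seed = 89)
  mt <- membraneThinning(g$frame, g$system, bin = 2)
  expect_equal(mt$bulk, 4, tolerance = 0.05)
  ## thickness at the annulus (centered bins near r = 8)
  ctr <- groundTruth(g)$center
  nx <- length(mt$xEdges) - 1L
  thin <- c()
  for (i in seq_len(nx)) for (j in seq_len(length(mt$yEdges) - 1L)) {
    bx <- (mt$xEdges[i] + mt$xEdges[i + 1]) / 2 - ctr[1]
    by <- (mt$yEdges[j] + mt$yEdges[j + 1]) / 2 - ctr[2]
    rr <- sqrt(bx^2 + by^2)
    if (rr > 6.8 && rr < 9.2) thin <- c(thin, mt$thickness[i, j])
  }
  expect_true(mean(thin, na.rm = TRUE) < 3.2)  # ~0.7 x bulk
})

test_that("bins missing a leaflet are NA rather than zero", {
  g <- synthMembranePatch(nInner = 30L, nOuter = 30L, area = 36,
                          seed = 90)
  pos <- coords(g$frame)
  box <- boxDims(g$frame)
  ## push all lipids into one quadrant so other bins are empty
  pos[, 1] <- pos[, 1] / 3
  f <- new("Frame", time = 0, coords = pos, box = box)
  mt <- membraneThinning(f, g$system, bin = 2)
  expect_true(any(is.na(mt$thickness)))
  expect_false(any(mt$thickness == 0, na.rm = TRUE))
})
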