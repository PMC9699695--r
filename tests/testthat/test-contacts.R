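test_that("contact cutoff is a strict boundary on min heavy-atom distance", {
  mk <- function(d) {
    sys <- poremetrics:::buildSystem(c("PO4", "CA"), c("POPS", "GLY"),
                                     1:2)
    frame <- new("Frame", time = 0,
                 coords = rbind(c(2, 2, 2), c(2 + d, 2, 2)),
                 box = c(6, 6, 6))
    heavyAtomContacts(frame, sys)
  }
  expect_equal(nrow(mk(0.30)), 1L)
  expect_equal(nrow(mk(0.37)), 0L)
  expect_equal(nrow(mk(0.36)), 1L)  # <= is inclusive
})

test_that("minimum image sees contacts across the periodic boundary", {
  sys <- poremetrics:::buildSystem(c("PO4", "CA"), c("POPS", "GLY"), 1:2)
  frame <- new("Frame", time = 0,
               coords = rbind(c(0.05, 3, 3), c(5.95, 3, 3)),
               box = c(6, 6, 6))
  cc <- heavyAtomContacts(frame, sys)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$dist, 0.1, tolerance = 1e-9)
})

test_that("a box smaller than twice the cutoff is rejected", {
  sys <- poremetrics:::buildSystem(c("PO4", "CA"), c("POPS", "GLY"), 1:2)
  frame <- new("Frame", time = 0,
               coords = rbind(c(0.1, 1, 1), c(0.3, 1, 1)),
               box = c(0.5, 6, 6))
  expect_error(heavyAtomContacts(frame, sys), "minimum image")
})

test_that("cell-list contacts equal all-pairs brute force", {
  for (seed in c(41, 42, 43)) {
    fx <- randomContactFixture(nLipids = 80L, nProtRes = 25L,
                               seed = seed)
    cc <- heavyAtomContacts(fx$frame, fx$system)
    pos <- coords(fx$frame)
    brute <- bruteContacts(pos[fx$lipidRows, , drop = FALSE],
                           pos[fx$protRows, , drop = FALSE],
                           boxDims(fx$frame), 0.36)
    ## reduce brute pairs to per-residue-pair minima
    at <- atoms(fx$system)
    if (nrow(brute)) {
      lipKey <- at$residueKey[fx$lipidRows[brute$i]]
      protKey <- at$residueKey[fx$protRows[brute$j]]
      agg <- aggregate(list(dist = brute$dist),
                       by = list(lipid = lipKey, protein = protKey),
                       FUN = min)
      agg <- agg[order(agg$lipid, agg$protein), ]
      expect_equal(cc$lipid, agg$lipid)
      expect_equal(cc$protein, agg$protein)
      expect_equal(cc$dist, agg$dist, tolerance = 1e-12)
    } else {
      expect_equal(nrow(cc), 0L)
    }
  }
})

test_that("cell list handles boxes barely above the minimum-image limit", {
  fx <- randomContactFixture(nLipids = 40L, nProtRes = 10L,
                             box = c(0.8, 0.8, 0.8), seed = 44)
  cc <- heavyAtomContacts(fx$frame, fx$system)
  pos <- coords(fx$frame)
  brute <- bruteContacts(pos[fx$lipidRows, , drop = FALSE],
                         pos[fx$protRows, , drop = FALSE],
                         c(0.8, 0.8, 0.8), 0.36)
  at <- atoms(fx$system)
  lipKey <- at$residueKey[fx$lipidRows[brute$i]]
  protKey <- at$residueKey[fx$protRows[brute$j]]
  agg <- aggregate(list(dist = brute$dist),
                   by = list(lipid = lipKey, protein = protKey),
                   FUN = min)
  expect_equal(nrow(cc), nrow(agg))
  expect_equal(sort(cc$dist), sort(agg$dist), tolerance = 1e-12)
})

test_that("dual-cutoff residence matches interval arithmetic", {
  d <- c(rep(0.3, 10), rep(0.45, 5), rep(0.6, 5))
  ri <- residenceIntervals(d)
  expect_equal(nrow(ri), 1L)
  expect_equal(ri$frames, 15L)
  expect_equal(ri$start, 0L)
  expect_equal(ri$end, 15L)
  oracle <- bruteResidence(d, 0.36, 0.50)
  expect_equal(unname(unlist(oracle)), c(0L, 15L))
})

test_that("all distances above the release cutoff give no intervals", {
  expect_equal(nrow(residenceIntervals(rep(0.6, 20))), 0L)
})

test_that("equal cutoffs reduce to single-cutoff segmentation", {
  d <- c(rep(0.3, 5), rep(0.45, 3), rep(0.3, 7), rep(0.9, 5))
  single <- residenceIntervals(d, releaseCutoff = 0.36)
  expect_equal(single$frames, c(5L, 7L))
  dual <- residenceIntervals(d)
  expect_equal(dual$frames, 15L)
})

test_that("residence is monotone in the release cutoff on random traces", {
  set.seed(45)
  for (k in 1:20) {
    d <- runif(200, 0.2, 1.0)
    dual <- residenceIntervals(d, 0.36, 0.50)
    single <- residenceIntervals(d, 0.36, 0.36)
    expect_gte(sum(dual$frames), sum(single$frames))
    ## and both agree with the brute-force oracle
    oDual <- bruteResidence(d, 0.36, 0.50)
    expect_equal(sum(dual$frames),
                 sum(vapply(oDual, diff, numeric(1))))
  }
})

test_that("planted occupancy is recovered", {
  sched <- data.frame(lipid = 1L, residue = 2L, start = 0L, end = 20L,
                      distance = 0.30)
  tr <- synthContactTraces(sched, nFrames = 40L)
  cc <- trajectoryContacts(tr$frames, tr$system)
  occ <- contactOccupancy(cc, tr$system, nFrames = 40L)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$occupancy, 0.5)
})

test_that("enrichment is ~1 under the abundance-proportional null", {
  set.seed(46)
  species <- c("POPS", "PIP2", "POPE")
  mf <- c(POPS = 0.5, PIP2 = 0.2, POPE = 0.3)
  draws <- sample(species, 3000, replace = TRUE, prob = mf)
  contacts <- data.frame(lipidResname = draws)
  enr <- speciesEnrichment(contacts, system = NULL,
                           moleFractions = mf)
  expect_true(all(abs(enr$enrichment - 1) < 0.1))
})

test_that("a species given 3x its abundance share is 3x enriched", {
  mf <- c(POPS = 0.8, PIP2 = 0.1)
  contacts <- data.frame(
    lipidResname = c(rep("PIP2", 30), rep("POPS", 70)))
  enr <- speciesEnrichment(contacts, system = NULL, moleFractions = mf)
  expect_equal(enr$enrichment[enr$species == "PIP2"], 3,
               tolerance = 1e-12)
})

test_that("bridging requires simultaneous contact with adjacent subunits", {
  ## lipid 1 bridges residues in subunits 1 and 2 for frames [5, 25);
  ## lipid 2 touches only subunit 1
  sched <- data.frame(lipid = c(1L, 1L, 2L),
                      residue = c(2L, 5L, 3L),
                      start = c(5L, 5L, 0L), end = c(25L, 25L, 30L),
                      distance = 0.30)
  tr <- synthContactTraces(sched, nFrames = 30L, nSubunits = 2L,
                           residuesPerSubunit = 4L)
  cc <- trajectoryContacts(tr$frames, tr$system)
  br <- bridgingLipids(cc, nSubunits = 2L, nFrames = 30L,
                       closed = FALSE)
  expect_equal(sum(br$perFrame$bridging), 20L)
  expect_equal(unname(rowSums(br$perInterface)["1-2"]), 20)
  expect_true(all(br$records$lipid == residues(tr$system)$key[
    match(9, residues(tr$system)$resid)]))
})

test_that("ring relabeling permutes bridging counts accordingly", {
  sched <- data.frame(lipid = 1L, residue = c(4L, 5L), start = 0L,
                      end = 10L, distance = 0.3)
  tr <- synthContactTraces(sched, nFrames = 10L, nSubunits = 4L,
                           residuesPerSubunit = 2L)
  cc <- trajectoryContacts(tr$frames, tr$system)
  br <- bridgingLipids(cc, nSubunits = 4L, nFrames = 10L, closed = TRUE)
  expect_equal(unname(rowSums(br$perInterface)),
               c(0, 10, 0, 0))
  ## rotate subunit labels by 1 (1->2, ..., 4->1): the bridge moves to
  ## the rotated interface
  cc2 <- cc
  cc2$subunit <- cc$subunit %% 4L + 1L
  br2 <- bridgingLipids(cc2, nSubunits = 4L, nFrames = 10L,
                        closed = TRUE)
  expect_equal(unname(rowSums(br2$perInterface)),
               c(0, 0, 10, 0))
})

test_that("bridging totals never exceed contacting lipids", {
  set.seed(47)
  sched <- data.frame(lipid = 1:3, residue = c(2L, 4L, 7L),
                      start = 0L, end = 15L, distance = 0.3)
  tr <- synthContactTraces(sched, nFrames = 15L, nSubunits = 4L,
                           residuesPerSubunit = 2L)
  cc <- trajectoryContacts(tr$frames, tr$system)
  br <- bridgingLipids(cc, nSubunits = 4L, nFrames = 15L, closed = TRUE)
  for (f in unique(cc$frame)) {
    nContacting <- length(unique(cc$lipid[cc$frame == f]))
    expect_lte(br$perFrame$bridging[f + 1], nContacting)
  }
})

test_that("fewer than two subunits cannot bridge", {
  expect_error(bridgingLipids(data.frame(), nSubunits = 1L,
                              nFrames = 5L), "at least 2")
})

test_that("analysis window drops the pre-equilibration frames", {
  frames <- lapply(0:9, function(k)
    new("Frame", time = k * 100, coords = matrix(0, 1, 3),
        box = c(1, 1, 1) * 10))
  kept <- analysisWindow(frames, discard = 500)
  expect_length(kept, 5L)
  expect_true(all(vapply(kept, frameTime, numeric(1)) >= 500))
})
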