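test_that("GRO parsing reads atoms, residues, species and box", {
  path <- writeTinyGRO(tempfile(fileext = ".gro"))
  s <- readGRO(path)
  expect_equal(nAtoms(s$system), 3L)
  expect_equal(boxDims(s$frame), c(10, 10, 10))
  expect_equal(coords(s$frame)[1, ], c(1, 2, 3))
  expect_equal(residues(s$system)$species, c("lipid", "water", "ion"))
  expect_equal(atoms(s$system)$element[1], "P")
  expect_true(all(atoms(s$system)$isHeavy))
})

test_that("malformed GRO files fail with the offending line named", {
  path <- tempfile(fileext = ".gro")
  writeLines(c("title", "    2",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1, "POPS", "P", 1, 1, 1, 1),
               "garbage line here padded to some width",
               "  10.0 10.0 10.0"), path)
  expect_error(readGRO(path), "malformed fixed columns")
  writeLines(c("title", "    1",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1, "POPS", "P", 1, 1, 1, 1)), path)
  expect_error(readGRO(path), "box")
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1  100.000  100.000  100.000  90.00  90.00  90.00 P 1",
    paste0("ATOM      1  N   ALA A   1      12.700   8.000   5.000",
           "  1.00  0.00           N"),
    paste0("ATOM      2  CA  ALA A   1      13.700   8.500   5.200",
           "  1.00  0.00           C"),
    "END"), path)
  s <- readPDB(path)
  expect_equal(coords(s$frame)[1, 1], 1.270, tolerance = 1e-9)
  expect_equal(boxDims(s$frame), c(10, 10, 10))
  expect_equal(residues(s$system)$species, "protein")
})

test_that("GRO write/read round-trips coordinates to format precision", {
  g <- synthMembranePatch(nInner = 20L, nOuter = 20L, area = 30,
                          seed = 11)
  path <- tempfile(fileext = ".gro")
  writeGRO(g$system, g$frame, path)
  back <- readGRO(path)
  expect_equal(nAtoms(back$system), nAtoms(g$system))
  expect_equal(coords(back$frame), round(coords(g$frame), 3),
               tolerance = 5e-4)
  expect_equal(atoms(back$system)$name, atoms(g$system)$name)
})

test_that("trajectory reader yields frames in order and checks counts", {
  g <- synthMembranePatch(nInner = 10L, nOuter = 10L, area = 20,
                          seed = 12)
  f2 <- new("Frame", time = 1.5, coords = coords(g$frame) + 0.1,
            box = boxDims(g$frame))
  path <- tempfile(fileext = ".gro")
  writeTrajectory(g$system, list(g$frame, f2), path)
  frames <- readTrajectory(path)
  expect_length(frames, 2L)
  expect_equal(vapply(frames, frameTime, numeric(1)), c(0, 1.5))
  ## empty file: zero frames, no error
  empty <- tempfile()
  file.create(empty)
  expect_length(readTrajectory(empty), 0L)
  ## atom-count change mid-file errors with the frame index
  bad <- tempfile(fileext = ".gro")
  writeLines(c(readLines(path)[1:43], readLines(writeTinyGRO(
    tempfile(fileext = ".gro")))), bad)
  expect_error(readTrajectory(bad), "frame index 1")
})

test_that("trajectory frames reproduce the generator output exactly", {
  g <- synthMembranePatch(nInner = 15L, nOuter = 15L, area = 25,
                          seed = 13)
  frames <- lapply(0:9, function(k)
    new("Frame", time = k * 0.5, coords = coords(g$frame) + 0.01 * k,
        box = boxDims(g$frame)))
  path <- tempfile(fileext = ".gro")
  writeTrajectory(g$system, frames, path)
  back <- readTrajectory(path)
  expect_equal(coords(back[[8]]), round(coords(frames[[8]]), 3),
               tolerance = 5e-4)
  expect_equal(frameTime(back[[8]]), 3.5)
})

test_that("leaflet assignment recovers the generator census", {
  g <- synthMembranePatch(nInner = 99L, nOuter = 100L, area = 72,
                          seed = 14)
  sys <- assignLeaflets(g$system, g$frame)
  tab <- table(residues(sys)$leaflet)
  expect_equal(as.integer(tab[["inner"]]), 99L)
  expect_equal(as.integer(tab[["outer"]]), 100L)
})

test_that("leaflet assignment is invariant under rigid z-translation", {
  g <- synthMembranePatch(nInner = 30L, nOuter = 30L, area = 30,
                          seed = 15)
  sys1 <- assignLeaflets(g$system, g$frame)
  shifted <- new("Frame", time = 0, coords = coords(g$frame) +
                   rep(c(0, 0, 3), each = nAtoms(g$frame)),
                 box = boxDims(g$frame) + c(0, 0, 6))
  sys2 <- assignLeaflets(g$system, shifted)
  expect_equal(residues(sys1)$leaflet, residues(sys2)$leaflet)
})

test_that("crown deformation below the leaflet separation keeps labels", {
  flat <- synthMembranePatch(nInner = 200L, nOuter = 200L, area = 400,
                             seed = 16)
  crowned <- synthMembranePatch(nInner = 200L, nOuter = 200L,
                                area = 400, crownHeight = 1.5,
                                ringRadius = 8, seed = 16)
  s1 <- assignLeaflets(flat$system, flat$frame)
  s2 <- assignLeaflets(crowned$system, crowned$frame)
  expect_equal(residues(s1)$leaflet, residues(s2)$leaflet)
})

test_that("single-leaflet sheets get one label with a warning", {
  g <- synthMembranePatch(nInner = 20L, nOuter = 20L, area = 30,
                          seed = 17)
  pos <- coords(g$frame)
  pos[, 3] <- 5  # collapse everything onto one plane
  flatFrame <- new("Frame", time = 0, coords = pos,
                   box = boxDims(g$frame))
  expect_warning(sys <- assignLeaflets(g$system, flatFrame),
                 "single-leaflet")
  expect_equal(unique(residues(sys)$leaflet), "outer")
})

test_that("no lipids means leaflet assignment refuses", {
  w <- synthWaterColumn(c(4, 8), seed = 1)
  expect_error(assignLeaflets(w$system, w$frame), "no lipids")
})

test_that("subunit assignment uses chains when present", {
  r <- synthRing(33L, seed = 18)
  sys <- residues(r$system)
  subs <- sys$subunit[sys$species == "protein"]
  expect_equal(sort(unique(subs)), 1:33)
  expect_equal(subs, groundTruth(r)$subunitOfResidue)
})

test_that("subunit assignment splits single chains into equal blocks", {
  n <- 660L
  sysOne <- poremetrics:::buildSystem(rep("CA", n), rep("GLY", n),
                                      seq_len(n))
  out <- assignSubunits(sysOne, 2L)
  subs <- residues(out)$subunit
  expect_equal(subs[1:330], rep(1L, 330))
  expect_equal(subs[331:660], rep(2L, 330))
  ## a disjoint cover of protein residues
  expect_false(any(is.na(subs)))
  expect_error(assignSubunits(sysOne, 7L), "not divisible")
})

test_that("16-mer ring subunits match the generator assignment", {
  r <- synthRing(16L, arcFraction = 16 / 33, seed = 19)
  expect_equal(residues(r$system)$subunit,
               groundTruth(r)$subunitOfResidue)
})
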