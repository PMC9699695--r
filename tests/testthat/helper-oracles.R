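## Independent brute-force oracles used to check the package's
## algorithmic implementations.  Kept deliberately naive.

## All-pairs minimum-image contact search (quadratic).
bruteContacts <- function(posA, posB, box, cutoff) {
  hits <- NULL
  for (i in seq_len(nrow(posA))) {
    for (j in seq_len(nrow(posB))) {
      d <- posA[i, ] - posB[j, ]
      d <- d - box * round(d / box)
      dist <- sqrt(sum(d^2))
      if (dist <= cutoff)
        hits <- rbind(hits, c(i = i, j = j, dist = dist))
    }
  }
  if (is.null(hits))
    data.frame(i = integer(), j = integer(), dist = numeric())
  else as.data.frame(hits)
}

## Literal dual-cutoff interval arithmetic on one distance vector.
## Returns total bound frames and the list of [start, end) intervals.
bruteResidence <- function(d, startCut, releaseCut) {
  intervals <- list()
  f <- 1L
  n <- length(d)
  while (f <= n) {
    if (d[f] <= startCut) {
      s <- f
      while (f <= n && d[f] <= releaseCut) f <- f + 1L
      intervals[[length(intervals) + 1L]] <- c(s - 1L, f - 1L)
    } else f <- f + 1L
  }
  intervals
}

## State-sequence enumeration of complete slab traversals on the
## unwrapped path.
bruteCrossings <- function(zw, zLow, zHigh, Lz) {
  dz <- diff(zw)
  dz <- dz - Lz * round(dz / Lz)
  zu <- cumsum(c(zw[1L], dz))
  zz <- zu %% Lz
  up <- 0L; down <- 0L
  entered <- NULL
  side <- NULL
  for (v in zz) {
    s <- if (v < zLow) "B" else if (v > zHigh) "A" else "I"
    if (s == "I") {
      if (is.null(entered)) entered <- side
    } else {
      if (!is.null(entered)) {
        if (identical(entered, "B") && s == "A") up <- up + 1L
        if (identical(entered, "A") && s == "B") down <- down + 1L
        entered <- NULL
      }
      side <- s
    }
  }
  c(up = up, down = down)
}

## Random mixed lipid/protein frame for contact-search testing.
randomContactFixture <- function(nLipids = 60L, nProtRes = 20L,
                                 atomsPerRes = 5L, box = c(6, 6, 6),
                                 seed = 1L) {
  set.seed(seed)
  nProtAtoms <- nProtRes * atomsPerRes
  name <- c(rep("PO4", nLipids), rep("CA", nProtAtoms))
  resname <- c(rep("POPS", nLipids), rep("GLY", nProtAtoms))
  resid <- c(seq_len(nLipids), nLipids + rep(seq_len(nProtRes),
                                             each = atomsPerRes))
  system <- poremetrics:::buildSystem(name, resname, resid)
  pos <- cbind(runif(nLipids + nProtAtoms, 0, box[1L]),
               runif(nLipids + nProtAtoms, 0, box[2L]),
               runif(nLipids + nProtAtoms, 0, box[3L]))
  frame <- new("Frame", time = 0, coords = pos, box = box)
  list(system = system, frame = frame, lipidRows = seq_len(nLipids),
       protRows = nLipids + seq_len(nProtAtoms))
}

## Tiny GRO text fixture written to a temp file.
writeTinyGRO <- function(path, box = "10.00000  10.00000  10.00000") {
  atomLine <- function(resid, resname, name, nr, x, y, z)
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", resid, resname, name, nr,
            x, y, z)
  writeLines(c(
    "tiny fixture t= 0.0",
    "    3",
    atomLine(1, "POPS", "P", 1, 1.0, 2.0, 3.0),
    atomLine(2, "SOL", "OW", 2, 4.5, 4.5, 4.5),
    atomLine(3, "NA", "NA", 3, 0.1, 0.2, 0.3),
    paste0("  ", box)), path)
  path
}
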