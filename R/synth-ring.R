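#' Synthetic oligomer ring or arc with hairpins
#'
#' Builds `nSubunits` protein pseudo-subunits placed at equal angular
#' spacing over a fraction `arcFraction` of a circle of radius
#' `ringRadius`.  Each subunit consists of a globular pseudo-domain (a
#' cluster of beads above the membrane plane, residue `GLB`), a hairpin
#' base bead (residue `HPB`) and a hairpin tip bead (residue `HPT`);
#' the base-to-tip vector makes the angle `hairpinTilt` with the
#' membrane (xy) plane, pointing radially inward and downward into the
#' membrane.  Subunits carry distinct chain identifiers so
#' [assignSubunits()] recovers the construction.
#'
#' @param nSubunits number of subunits (>= 1).
#' @param ringRadius circle radius in nm.
#' @param arcFraction fraction of the full circle covered, in (0, 1].
#' @param hairpinTilt hairpin tilt angle(s) vs the membrane plane, in
#'   degrees; recycled over subunits.
#' @param hairpinLength base-to-tip distance in nm.
#' @param membraneZ z of the membrane plane in nm.
#' @param domainSpread sd of the globular bead cluster in nm.
#' @param domainBeads beads per globular domain.
#' @param seed RNG seed.
#' @return list(system, frame) with a `groundTruth` attribute.
#' @export
synthRing <- function(nSubunits, ringRadius = 10, arcFraction = 1,
                      hairpinTilt = 55, hairpinLength = 2.5,
                      membraneZ = 5, domainSpread = 0.3,
                      domainBeads = 12L, seed = NULL) {
  stopifnot(nSubunits >= 1, arcFraction > 0, arcFraction <= 1,
            ringRadius > 0)
  tilt <- rep_len(hairpinTilt, nSubunits)
  L <- 2 * ringRadius + 10
  center <- c(L, L) / 2
  delta <- 2 * pi * arcFraction / nSubunits
  theta <- (seq_len(nSubunits) - 1L) * delta
  name <- character(0); resname <- character(0); resid <- integer(0)
  chain <- character(0); pos <- NULL
  subCentroid <- matrix(NA_real_, nSubunits, 2L)
  rid <- 0L
  noise <- withSeed(seed,
    matrix(rnorm(nSubunits * domainBeads * 3L, 0, domainSpread),
           ncol = 3L))
  for (k in seq_len(nSubunits)) {
    cx <- center[1L] + ringRadius * cos(theta[k])
    cy <- center[2L] + ringRadius * sin(theta[k])
    ck <- sprintf("S%03d", k)
    ## globular domain: one residue of `domainBeads` beads above the plane
    gNoise <- noise[(k - 1L) * domainBeads + seq_len(domainBeads), ,
                    drop = FALSE]
    gPos <- cbind(cx + gNoise[, 1L], cy + gNoise[, 2L],
                  membraneZ + 1.8 + gNoise[, 3L])
    rid <- rid + 1L
    name <- c(name, rep("BB", domainBeads))
    resname <- c(resname, rep("GLB", domainBeads))
    resid <- c(resid, rep(rid, domainBeads))
    chain <- c(chain, rep(ck, domainBeads))
    pos <- rbind(pos, gPos)
    subCentroid[k, ] <- c(mean(gPos[, 1L]), mean(gPos[, 2L]))
    ## hairpin: base at the plane, tip inward and down at the set tilt
    inward <- -c(cos(theta[k]), sin(theta[k]))
    a <- tilt[k] * pi / 180
    base <- c(cx, cy, membraneZ + 0.2)
    tipv <- c(hairpinLength * cos(a) * inward,
              -hairpinLength * sin(a))
    tip <- base + tipv
    rid <- rid + 1L
    name <- c(name, "BAS"); resname <- c(resname, "HPB")
    resid <- c(resid, rid); chain <- c(chain, ck)
    pos <- rbind(pos, base)
    rid <- rid + 1L
    name <- c(name, "TIP"); resname <- c(resname, "HPT")
    resid <- c(resid, rid); chain <- c(chain, ck)
    pos <- rbind(pos, tip)
  }
  system <- buildSystem(name, resname, resid, chain)
  system <- assignSubunits(system)
  frame <- new("Frame", time = 0, coords = unname(pos),
               box = c(L, L, 2 * membraneZ + 4))
  out <- list(system = system, frame = frame)
  attr(out, "groundTruth") <- list(
    generator = "synth_ring", seed = seed, nSubunits = nSubunits,
    ringRadius = ringRadius, arcFraction = arcFraction,
    gapAngle = 2 * pi * (1 - arcFraction), hairpinTilt = tilt,
    center = center, membraneZ = membraneZ, theta = theta,
    subunitCentroids = subCentroid,
    subunitOfResidue = residues(system)$subunit)
  out
}

#' Synthetic inter-subunit contact-count series with a planted crack
#'
#' Produces the per-interface contact-count time series that the crack
#' detector consumes: adjacent-subunit interfaces of an arc (or ring)
#' hold a healthy baseline contact count; at `crackFrame` the planted
#' interface drops to near zero and stays there.
#'
#' @param nSubunits subunits in the arc/ring.
#' @param crackInterface integer pair `c(i, i+1)` (or single index i) of
#'   the interface that cracks, or NULL for no crack.
#' @param crackFrame 0-based frame at which contact is lost.
#' @param nFrames total frames.
#' @param baseline mean healthy contact count.
#' @param closed TRUE for a ring (adds interface (n, 1)).
#' @param seed RNG seed.
#' @return matrix interfaces x frames with rownames "i-j" and a
#'   `groundTruth` attribute.
#' @export
synthCrackSeries <- function(nSubunits, crackInterface = NULL,
                             crackFrame = NULL, nFrames = 1000L,
                             baseline = 20, closed = FALSE, seed = NULL) {
  stopifnot(nSubunits >= 2)
  iFirst <- seq_len(if (closed) nSubunits else nSubunits - 1L)
  iSecond <- iFirst %% nSubunits + 1L
  labels <- paste(iFirst, iSecond, sep = "-")
  counts <- withSeed(seed, {
    m <- matrix(stats::rpois(length(iFirst) * nFrames, baseline),
                nrow = length(iFirst))
    if (!is.null(crackInterface)) {
      i <- crackInterface[1L]
      row <- match(paste(i, i %% nSubunits + 1L, sep = "-"), labels)
      if (is.na(row)) stop("interface ", i, " not present")
      post <- (crackFrame + 1L):nFrames
      m[row, post] <- stats::rpois(length(post), 0.3)
    }
    m
  })
  rownames(counts) <- labels
  attr(counts, "groundTruth") <- list(
    generator = "synth_crack_series", seed = seed, nSubunits = nSubunits,
    crackInterface = crackInterface, crackFrame = crackFrame,
    baseline = baseline, closed = closed)
  counts
}
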