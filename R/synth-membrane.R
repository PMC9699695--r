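#' Synthetic bilayer patch with optional pore, crown and thinning
#'
#' Places one headgroup pseudo-atom per lipid on two z-planes (leaflet
#' separation `leafletSep`, i.e. +/- `leafletSep/2` about the midplane)
#' by rejection sampling over a square patch.  Optionally a lipid-free
#' disc of radius `poreRadius` at the patch center, a crown deformation
#' (lipids with radial distance r < `ringRadius` raised by
#' `crownHeight * (1 - r/ringRadius)`, a linear profile), and an annular
#' thinning region where the leaflet separation is scaled by
#' `thinning$factor`.
#'
#' @param nInner,nOuter lipid counts per leaflet; either plain integers
#'   (species "POPC") or named integer vectors (resname -> count; names
#'   in the sterol dictionary become sterols with a hydroxyl bead).
#' @param area patch area in nm^2 (square side `sqrt(area)`).
#' @param poreRadius lipid-free disc radius in nm, or NULL.
#' @param crownHeight,ringRadius crown deformation parameters in nm, or
#'   NULL for a flat patch.
#' @param thinning NULL or `list(rIn=, rOut=, factor=)`: inside the
#'   annulus `rIn <= r < rOut` the leaflet separation is multiplied by
#'   `factor`.
#' @param leafletSep inter-leaflet headgroup separation in nm.
#' @param zJitter per-lipid z noise sd in nm.
#' @param waterSpace solvent slab added above and below, sets Lz.
#' @param seed RNG seed.
#' @return list(system, frame) with a `groundTruth` attribute.
#' @export
synthMembranePatch <- function(nInner = 99L, nOuter = 100L, area = 72,
                               poreRadius = NULL, crownHeight = NULL,
                               ringRadius = NULL, thinning = NULL,
                               leafletSep = 4, zJitter = 0.05,
                               waterSpace = 4, seed = NULL) {
  stopifnot(area > 0, leafletSep > 0)
  L <- sqrt(area)
  center <- c(L, L) / 2
  usable <- area - if (is.null(poreRadius)) 0 else pi * poreRadius^2
  apl <- 0.65  # nm^2 per phospholipid headgroup
  perLeaflet <- c(sum(nInner), sum(nOuter))
  if (any(perLeaflet * apl > usable))
    stop("overcrowded patch: ", max(perLeaflet), " lipids need >= ",
         sprintf("%.1f", max(perLeaflet) * apl),
         " nm^2 of free area but only ", sprintf("%.1f", usable),
         " nm^2 available")
  Lz <- leafletSep + 2 * waterSpace
  mid <- Lz / 2

  sampleXY <- function(n) {
    pts <- matrix(NA_real_, 0L, 2L)
    while (nrow(pts) < n) {
      m <- max(2L * (n - nrow(pts)), 16L)
      cand <- cbind(runif(m, 0, L), runif(m, 0, L))
      if (!is.null(poreRadius)) {
        r <- sqrt((cand[, 1L] - center[1L])^2 + (cand[, 2L] - center[2L])^2)
        cand <- cand[r >= poreRadius, , drop = FALSE]
      }
      pts <- rbind(pts, cand)
    }
    pts[seq_len(n), , drop = FALSE]
  }

  expandPlan <- function(plan) {
    if (is.null(names(plan))) return(rep("POPC", sum(plan)))
    rep(names(plan), as.integer(plan))
  }

  withSeed(seed, {
    innerSpecies <- expandPlan(nInner)
    outerSpecies <- expandPlan(nOuter)
    xyI <- sampleXY(length(innerSpecies))
    xyO <- sampleXY(length(outerSpecies))
    jI <- rnorm(length(innerSpecies), 0, zJitter)
    jO <- rnorm(length(outerSpecies), 0, zJitter)
  })

  placeLeaflet <- function(xy, sign, jitter) {
    off <- rep(sign * leafletSep / 2, nrow(xy))
    r <- sqrt((xy[, 1L] - center[1L])^2 + (xy[, 2L] - center[2L])^2)
    if (!is.null(thinning)) {
      inAnn <- r >= thinning$rIn & r < thinning$rOut
      off[inAnn] <- off[inAnn] * thinning$factor
    }
    z <- mid + off + jitter
    if (!is.null(crownHeight)) {
      stopifnot(!is.null(ringRadius))
      lift <- ifelse(r < ringRadius, crownHeight * (1 - r / ringRadius), 0)
      z <- z + lift
    }
    cbind(xy, z)
  }

  posI <- placeLeaflet(xyI, -1, jI)
  posO <- placeLeaflet(xyO, +1, jO)
  species <- c(innerSpecies, outerSpecies)
  isSterol <- toupper(species) %in% STEROL_RESNAMES
  ## two beads per lipid: the headgroup reference and a hydrocarbon-core
  ## bead at the midplane (so the bilayer core is physically occupied,
  ## as it is for chemically complete lipids)
  headPos <- rbind(posI, posO)
  xyAll <- rbind(xyI, xyO)
  rAll <- sqrt((xyAll[, 1L] - center[1L])^2 +
                 (xyAll[, 2L] - center[2L])^2)
  lift <- if (!is.null(crownHeight))
    ifelse(rAll < ringRadius, crownHeight * (1 - rAll / ringRadius), 0)
  else 0
  tailPos <- cbind(xyAll, mid + lift)
  n <- length(species)
  headName <- ifelse(isSterol, "ROH", "PO4")
  name <- as.vector(rbind(headName, rep("C2", n)))
  resname <- rep(species, each = 2L)
  resid <- rep(seq_len(n), each = 2L)
  coordsAll <- matrix(NA_real_, 2L * n, 3L)
  coordsAll[seq(1L, 2L * n, by = 2L), ] <- headPos
  coordsAll[seq(2L, 2L * n, by = 2L), ] <- tailPos
  system <- buildSystem(name = name, resname = resname, resid = resid)
  frame <- new("Frame", time = 0, coords = coordsAll,
               box = c(L, L, Lz))
  out <- list(system = system, frame = frame)
  attr(out, "groundTruth") <- list(
    generator = "synth_membrane_patch", seed = seed,
    nInner = length(innerSpecies), nOuter = length(outerSpecies),
    innerKeys = seq_along(innerSpecies),
    outerKeys = length(innerSpecies) + seq_along(outerSpecies),
    area = area, center = center, poreRadius = poreRadius,
    crownHeight = crownHeight, ringRadius = ringRadius,
    thinning = thinning, leafletSep = leafletSep, midplane = mid,
    box = c(L, L, Lz))
  out
}

#' Synthetic water column inside a pore
#'
#' Places water-oxygen pseudo-atoms in a cylinder spanning `zRange`,
#' several per `binDz` bin, skipping the bins listed in `gapBins`
#' (1-based).  Used to test the water-column continuity criterion.
#'
#' @param zRange numeric length-2, z extent in nm.
#' @param center cylinder axis (x, y) in nm.
#' @param radius cylinder radius in nm.
#' @param binDz bin height in nm.
#' @param gapBins indices of bins left empty.
#' @param perBin waters per bin.
#' @param box box lengths (nm).
#' @param seed RNG seed.
#' @return list(system, frame) with a `groundTruth` attribute.
#' @export
synthWaterColumn <- function(zRange, center = c(5, 5), radius = 1,
                             binDz = 0.3, gapBins = integer(0),
                             perBin = 3L, box = c(10, 10, 12),
                             seed = NULL) {
  stopifnot(length(zRange) == 2L, zRange[1L] < zRange[2L])
  edges <- seq(zRange[1L], zRange[2L], by = binDz)
  if (edges[length(edges)] < zRange[2L]) edges <- c(edges, zRange[2L])
  nb <- length(edges) - 1L
  keep <- setdiff(seq_len(nb), gapBins)
  pos <- withSeed(seed, {
    do.call(rbind, lapply(keep, function(b) {
      theta <- runif(perBin, 0, 2 * pi)
      rr <- radius * 0.8 * sqrt(runif(perBin))
      cbind(center[1L] + rr * cos(theta), center[2L] + rr * sin(theta),
            runif(perBin, edges[b], edges[b + 1L]))
    }))
  })
  if (is.null(pos)) pos <- matrix(numeric(0), 0L, 3L)
  n <- nrow(pos)
  system <- buildSystem(name = rep("OW", n), resname = rep("SOL", n),
                        resid = seq_len(n))
  frame <- new("Frame", time = 0, coords = unname(pos), box = box)
  out <- list(system = system, frame = frame)
  attr(out, "groundTruth") <- list(
    generator = "synth_water_column", seed = seed, zRange = zRange,
    center = center, radius = radius, binDz = binDz, gapBins = gapBins,
    nBins = nb)
  out
}
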