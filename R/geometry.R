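## Pore and membrane geometry observables.

## Default analysis center: protein centroid when a protein is present,
## else the lateral box center.
analysisCenter <- function(frame, system) {
  at <- system@atoms
  sp <- system@residues$species[at$residueKey]
  prot <- which(sp == "protein")
  if (length(prot))
    colMeans(frame@coords[prot, 1:2, drop = FALSE])
  else frame@box[1:2] / 2
}

#' Pore radius by largest inscribed disc on a rasterized midplane slab
#'
#' Lipid heavy atoms within `slabHalfWidth` of the membrane midplane are
#' rasterized onto an (x, y) grid; empty cells reachable from the
#' analysis center (protein-ring centroid, else patch center) are found
#' by flood fill, and the pore radius is the radius of the largest disc
#' centered there that stays inside the empty region.  Returns "no
#' pore" when the center cell is occupied or the disc is smaller than
#' one grid cell.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem].
#' @param slabHalfWidth half-width of the midplane slab in nm.
#' @param grid raster cell size in nm (must be <= 2 nm).
#' @param center optional (x, y) center override.
#' @return list(hasPore, radius, diameter, center, grid, method).
#' @export
poreRadius <- function(frame, system, slabHalfWidth = 1.0, grid = 0.5,
                       center = NULL) {
  if (grid > 2) stop("grid coarser than 2 nm")
  at <- system@atoms
  sp <- system@residues$species[at$residueKey]
  lip <- which(sp %in% c("lipid", "sterol") & at$isHeavy)
  if (!length(lip)) stop("no lipid atoms: no membrane present")
  pos <- frame@coords[lip, , drop = FALSE]
  mid <- mean(referenceZ(system, frame))
  inSlab <- abs(pos[, 3L] - mid) <= slabHalfWidth
  pos <- pos[inSlab, , drop = FALSE]
  if (is.null(center)) center <- analysisCenter(frame, system)
  nx <- max(2L, ceiling(frame@box[1L] / grid))
  ny <- max(2L, ceiling(frame@box[2L] / grid))
  occ <- matrix(FALSE, nx, ny)
  if (nrow(pos)) {
    ix <- pmin(pmax(floor(pos[, 1L] / grid) + 1L, 1L), nx)
    iy <- pmin(pmax(floor(pos[, 2L] / grid) + 1L, 1L), ny)
    occ[cbind(ix, iy)] <- TRUE
  }
  ci <- pmin(pmax(floor(center[1L] / grid) + 1L, 1L), nx)
  cj <- pmin(pmax(floor(center[2L] / grid) + 1L, 1L), ny)
  noPore <- list(hasPore = FALSE, radius = 0, diameter = 0,
                 center = center, grid = grid,
                 method = "inscribed-disc/flood-fill")
  if (occ[ci, cj]) return(noPore)
  ## flood fill the empty region reachable from the center (4-neighbor)
  reach <- matrix(FALSE, nx, ny)
  queue <- matrix(c(ci, cj), ncol = 2L)
  reach[ci, cj] <- TRUE
  while (nrow(queue)) {
    nxt <- matrix(integer(0), 0L, 2L)
    for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      cand <- cbind(queue[, 1L] + d[1L], queue[, 2L] + d[2L])
      ok <- cand[, 1L] >= 1L & cand[, 1L] <= nx &
        cand[, 2L] >= 1L & cand[, 2L] <= ny
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      new <- !reach[cand] & !occ[cand]
      cand <- cand[new, , drop = FALSE]
      if (nrow(cand)) {
        reach[cand] <- TRUE
        nxt <- rbind(nxt, cand)
      }
    }
    queue <- unique(nxt)
  }
  ## largest disc centered at the center inside the empty region.  The
  ## raster decides whether an open, center-connected region exists; the
  ## radius itself is refined against the actual atom positions (the
  ## region boundary), which removes the raster discretization noise of
  ## sparsely occupied cells.
  if (nrow(pos)) {
    dAtom <- sqrt((pos[, 1L] - center[1L])^2 +
                    (pos[, 2L] - center[2L])^2)
    radius <- min(dAtom)
  } else {
    radius <- min(center[1L], frame@box[1L] - center[1L],
                  center[2L], frame@box[2L] - center[2L])
  }
  if (radius <= max(grid, 1.0)) return(noPore)
  list(hasPore = TRUE, radius = radius, diameter = 2 * radius,
       center = center, grid = grid, regionCells = sum(reach),
       method = "inscribed-disc/flood-fill")
}

#' Radial membrane deformation (crown) profile
#'
#' Per-leaflet radial binning of headgroup reference z about the
#' analysis center.  The far-field reference is the mean z over the
#' outermost `farFieldFraction` of the radial range; the crown height
#' is the maximum binned z (outer leaflet) minus that reference.
#' Invariant under rigid z-translation of the whole frame.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem] with leaflets assigned (assigned on
#'   the fly when needed).
#' @param binDr radial bin width in nm.
#' @param farFieldFraction outermost fraction of radii defining the
#'   far-field reference.
#' @param center optional (x, y) center override.
#' @param minCount bins with fewer reference atoms than this are
#'   reported as NA.
#' @return list(profile = data.frame(r, zInner, zOuter, nInner, nOuter),
#'   farField, crownHeight).
#' @export
deformationProfile <- function(frame, system, binDr = 1.0,
                               farFieldFraction = 0.2, center = NULL,
                               minCount = 3L) {
  res <- system@residues
  if (all(res$leaflet[res$species %in% c("lipid", "sterol")] ==
            "unassigned"))
    system <- assignLeaflets(system, frame)
  res <- system@residues
  if (is.null(center)) center <- analysisCenter(frame, system)
  zref <- referenceZ(system, frame)
  keys <- as.integer(names(zref))
  leaf <- res$leaflet[match(keys, res$key)]
  at <- system@atoms
  xy <- t(vapply(keys, function(k) {
    rows <- which(at$residueKey == k)
    colMeans(frame@coords[rows, 1:2, drop = FALSE])
  }, numeric(2L)))
  r <- sqrt((xy[, 1L] - center[1L])^2 + (xy[, 2L] - center[2L])^2)
  rMax <- max(r)
  edges <- seq(0, rMax + binDr, by = binDr)
  bin <- findInterval(r, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  stat <- function(sel) {
    vapply(seq_len(nb), function(b) {
      v <- zref[sel & bin == b]
      if (length(v) >= minCount) mean(v) else NA_real_
    }, numeric(1L))
  }
  cnt <- function(sel) vapply(seq_len(nb), function(b)
    sum(sel & bin == b), integer(1L))
  rMean <- function(sel) vapply(seq_len(nb), function(b) {
    v <- r[sel & bin == b]
    if (length(v) >= minCount) mean(v) else NA_real_
  }, numeric(1L))
  inner <- leaf == "inner"; outer <- leaf == "outer"
  prof <- data.frame(r = edges[-length(edges)] + binDr / 2,
                     rMeanOuter = rMean(outer),
                     zInner = stat(inner), zOuter = stat(outer),
                     nInner = cnt(inner), nOuter = cnt(outer))
  farSel <- r >= (1 - farFieldFraction) * rMax & outer
  farField <- mean(zref[farSel])
  ## the profile peaks on the axis; extrapolate the two innermost valid
  ## bins to r = 0 (using the actual mean radius per bin, which makes
  ## the estimate exact for a locally linear profile), never below the
  ## binned maximum
  valid <- which(!is.na(prof$zOuter))
  apex <- max(prof$zOuter, na.rm = TRUE)
  if (length(valid) >= 2L) {
    b1 <- valid[1L]; b2 <- valid[2L]
    r1 <- prof$rMeanOuter[b1]; r2 <- prof$rMeanOuter[b2]
    z1 <- prof$zOuter[b1]; z2 <- prof$zOuter[b2]
    if (z1 > z2 && r2 > r1)
      apex <- max(apex, z1 + (z1 - z2) * r1 / (r2 - r1))
  }
  crownHeight <- apex - farField
  list(profile = prof, farField = farField, crownHeight = crownHeight)
}

#' Local membrane thickness map
#'
#' Per (x, y) bin, the mean upper-leaflet headgroup z minus the mean
#' lower-leaflet headgroup z.  Bins missing either leaflet are NA, not
#' zero.  The bulk reference is the median thickness over valid bins.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem] with leaflets assigned (assigned on
#'   the fly when needed).
#' @param bin lateral bin size in nm.
#' @return list(thickness = matrix (x-bins x y-bins), xEdges, yEdges,
#'   bulk).
#' @export
membraneThinning <- function(frame, system, bin = 2.0) {
  res <- system@residues
  if (all(res$leaflet[res$species %in% c("lipid", "sterol")] ==
            "unassigned"))
    system <- assignLeaflets(system, frame)
  res <- system@residues
  zref <- referenceZ(system, frame)
  keys <- as.integer(names(zref))
  leaf <- res$leaflet[match(keys, res$key)]
  at <- system@atoms
  xy <- t(vapply(keys, function(k) {
    rows <- which(at$residueKey == k)
    colMeans(frame@coords[rows, 1:2, drop = FALSE])
  }, numeric(2L)))
  xEdges <- seq(0, frame@box[1L] + bin, by = bin)
  yEdges <- seq(0, frame@box[2L] + bin, by = bin)
  ix <- findInterval(xy[, 1L], xEdges, rightmost.closed = TRUE)
  iy <- findInterval(xy[, 2L], yEdges, rightmost.closed = TRUE)
  nx <- length(xEdges) - 1L; ny <- length(yEdges) - 1L
  thick <- matrix(NA_real_, nx, ny)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    sel <- ix == i & iy == j
    up <- zref[sel & leaf == "outer"]
    lo <- zref[sel & leaf == "inner"]
    if (length(up) && length(lo)) thick[i, j] <- mean(up) - mean(lo)
  }
  list(thickness = thick, xEdges = xEdges, yEdges = yEdges,
       bulk = median(thick, na.rm = TRUE))
}

#' Hairpin (or helix) tilt angle versus the membrane plane
#'
#' Per subunit, the angle between the base-to-tip centroid vector and
#' the membrane (xy) plane: 90 degrees for a vector along z, 0 for an
#' in-plane vector.  Selections are residue names (default the
#' synthetic generator's hairpin base/tip pseudo-residues).
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem] with subunits assigned.
#' @param baseResname,tipResname residue names of the base and tip
#'   selections.
#' @return data.frame(subunit, tilt) in degrees.
#' @export
hairpinTilt <- function(frame, system, baseResname = "HPB",
                        tipResname = "HPT") {
  res <- system@residues
  at <- system@atoms
  subs <- sort(unique(res$subunit[!is.na(res$subunit)]))
  if (!length(subs)) stop("subunits not assigned")
  tilt <- vapply(subs, function(s) {
    keys <- res$key[!is.na(res$subunit) & res$subunit == s]
    baseRows <- which(at$residueKey %in%
                        keys[res$resname[keys] == baseResname])
    tipRows <- which(at$residueKey %in%
                       keys[res$resname[keys] == tipResname])
    if (!length(baseRows) || !length(tipRows)) return(NA_real_)
    v <- colMeans(frame@coords[tipRows, , drop = FALSE]) -
      colMeans(frame@coords[baseRows, , drop = FALSE])
    asin(abs(v[3L]) / sqrt(sum(v^2))) * 180 / pi
  }, numeric(1L))
  data.frame(subunit = subs, tilt = tilt)
}

#' Algebraic (Kasa) circle fit
#'
#' Closed-form least-squares circle through 2-D points; returns the
#' center, radius and the RMS of the radial residuals (0 for exact
#' circles, to numerical tolerance).
#'
#' @param xy n x 2 matrix of points (n >= 3).
#' @return list(center, radius, rms).
#' @export
circleFit <- function(xy) {
  if (nrow(xy) < 3L) stop("circle fit needs at least 3 points")
  A <- cbind(2 * xy[, 1L], 2 * xy[, 2L], 1)
  b <- xy[, 1L]^2 + xy[, 2L]^2
  sol <- qr.solve(A, b)
  ctr <- sol[1:2]
  radius <- sqrt(sol[3L] + sum(ctr^2))
  d <- sqrt((xy[, 1L] - ctr[1L])^2 + (xy[, 2L] - ctr[2L])^2)
  list(center = unname(ctr), radius = unname(radius),
       rms = sqrt(mean((d - radius)^2)))
}

#' Ring circularity from subunit centroids
#'
#' Fits a circle to the globular-domain centroids of all subunits and
#' reports the fit plus per-subunit radial deviations.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem] with subunits assigned.
#' @param domainResname residue name of the globular domain selection.
#' @return list(fit = [circleFit()] result, centroids).
#' @export
ringCircularity <- function(frame, system, domainResname = "GLB") {
  res <- system@residues
  at <- system@atoms
  subs <- sort(unique(res$subunit[!is.na(res$subunit)]))
  if (length(subs) < 3L) stop("circularity undefined for < 3 subunits")
  ctr <- t(vapply(subs, function(s) {
    keys <- res$key[!is.na(res$subunit) & res$subunit == s]
    gl <- keys[res$resname[keys] == domainResname]
    if (!length(gl)) gl <- keys
    rows <- which(at$residueKey %in% gl & at$isHeavy)
    colMeans(frame@coords[rows, 1:2, drop = FALSE])
  }, numeric(2L)))
  list(fit = circleFit(ctr), centroids = ctr)
}

#' Inter-subunit globular contact counts in one frame
#'
#' Heavy-atom contact counts (pairs within `cutoff`) between the
#' globular domains of each pair of adjacent subunits -- the quantity
#' whose persistent loss defines an arc crack.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem] with subunits assigned.
#' @param cutoff contact cutoff in nm.
#' @param closed include the (n, 1) interface.
#' @param domainResname globular-domain residue name.
#' @return named integer vector, names "i-j".
#' @export
subunitContactCounts <- function(frame, system, cutoff = 0.36,
                                 closed = FALSE, domainResname = "GLB") {
  res <- system@residues
  at <- system@atoms
  subs <- sort(unique(res$subunit[!is.na(res$subunit)]))
  n <- length(subs)
  if (n < 2L) stop("need at least 2 subunits")
  rowsOf <- lapply(subs, function(s) {
    keys <- res$key[!is.na(res$subunit) & res$subunit == s]
    gl <- keys[res$resname[keys] == domainResname]
    if (!length(gl)) gl <- keys
    which(at$residueKey %in% gl & at$isHeavy)
  })
  iFirst <- seq_len(if (closed) n else n - 1L)
  iSecond <- iFirst %% n + 1L
  counts <- vapply(seq_along(iFirst), function(k) {
    a <- frame@coords[rowsOf[[iFirst[k]]], , drop = FALSE]
    b <- frame@coords[rowsOf[[iSecond[k]]], , drop = FALSE]
    hits <- pairWithinCutoff(a, b, frame@box, cutoff)
    nrow(hits)
  }, integer(1L))
  setNames(counts, paste(subs[iFirst], subs[iSecond], sep = "-"))
}

#' Detect arc cracks from interface contact-count series
#'
#' An interface is cracked at the first frame where its inter-subunit
#' contact count stays below `threshold` for at least `persistence`
#' consecutive frames (both configurable; a zero threshold can never
#' crack).  Reports one row per cracked interface with the crack time.
#'
#' @param counts interfaces x frames matrix (rownames "i-j"), e.g. from
#'   [subunitContactCounts()] over frames or [synthCrackSeries()].
#' @param threshold contact count below which an interface is
#'   considered broken.
#' @param persistence minimum run length in frames.
#' @param dt frame spacing in ns.
#' @return data.frame(interface, crackFrame, crackTime) -- empty when
#'   nothing cracked.
#' @export
detectCracks <- function(counts, threshold = 5, persistence = 50L,
                         dt = 1) {
  out <- lapply(seq_len(nrow(counts)), function(r) {
    low <- counts[r, ] < threshold
    rl <- rle(low)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    hit <- which(rl$values & rl$lengths >= persistence)
    if (!length(hit)) return(NULL)
    f0 <- starts[hit[1L]] - 1L  # 0-based crack frame
    data.frame(interface = rownames(counts)[r], crackFrame = f0,
               crackTime = f0 * dt)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out))
    return(data.frame(interface = character(), crackFrame = integer(),
                      crackTime = numeric()))
  do.call(rbind, out)
}
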