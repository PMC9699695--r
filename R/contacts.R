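## Heavy-atom lipid-protein contact detection via a cell list under the
## minimum-image convention, plus the statistics built on it.

## All atom pairs (i from posA, j from posB) with minimum-image distance
## <= cutoff, found with a cell list (expected O(N)).  Positions are nm
## matrices; box an orthorhombic length-3 vector.
pairWithinCutoff <- function(posA, posB, box, cutoff) {
  if (any(box < 2 * cutoff))
    stop("box smaller than twice the cutoff: minimum image invalid")
  nc <- pmax(1L, floor(box / cutoff))
  cellSize <- box / nc
  wrap <- function(p) sweep(p, 2L, box, `%%`)
  pa <- wrap(posA); pb <- wrap(posB)
  cellIdx <- function(p) {
    idx <- floor(sweep(p, 2L, cellSize, `/`))
    for (d in 1:3) idx[, d] <- pmin(pmax(idx[, d], 0L), nc[d] - 1L)
    idx
  }
  ia <- cellIdx(pa); ib <- cellIdx(pb)
  keyOf <- function(idx) idx[, 1L] + nc[1L] * (idx[, 2L] + nc[2L] * idx[, 3L])
  bByKey <- split(seq_len(nrow(pb)), keyOf(ib))
  aKeys <- keyOf(ia)
  resI <- integer(0); resJ <- integer(0); resD <- numeric(0)
  for (key in unique(aKeys)) {
    aIdx <- which(aKeys == key)
    cx <- key %% nc[1L]
    cy <- (key %/% nc[1L]) %% nc[2L]
    cz <- key %/% (nc[1L] * nc[2L])
    neigh <- expand.grid(x = (cx + -1:1) %% nc[1L],
                         y = (cy + -1:1) %% nc[2L],
                         z = (cz + -1:1) %% nc[3L])
    nKeys <- unique(neigh$x + nc[1L] * (neigh$y + nc[2L] * neigh$z))
    bIdx <- unlist(bByKey[as.character(nKeys)], use.names = FALSE)
    if (!length(bIdx)) next
    for (i in aIdx) {
      d <- pb[bIdx, , drop = FALSE]
      d[, 1L] <- minImage(d[, 1L] - pa[i, 1L], box[1L])
      d[, 2L] <- minImage(d[, 2L] - pa[i, 2L], box[2L])
      d[, 3L] <- minImage(d[, 3L] - pa[i, 3L], box[3L])
      dist <- sqrt(rowSums(d^2))
      hit <- which(dist <= cutoff)
      if (length(hit)) {
        resI <- c(resI, rep.int(i, length(hit)))
        resJ <- c(resJ, bIdx[hit])
        resD <- c(resD, dist[hit])
      }
    }
  }
  data.frame(i = resI, j = resJ, dist = resD)
}

#' Heavy-atom lipid-protein contacts in one frame
#'
#' For every (lipid residue, protein residue) pair, the minimum distance
#' over lipid headgroup heavy atoms x protein heavy atoms is computed
#' under the minimum-image convention; pairs with a minimum distance at
#' or below `cutoff` (strict `<=`) are emitted.  Hydrogens are excluded
#' on both sides.  Uses a cell list, so the cost is linear in the atom
#' count for liquid-like densities.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem]; headgroup selections come from its
#'   headgroup table.
#' @param cutoff contact cutoff in nm (default 0.36, i.e. 3.6 Angstrom).
#' @param headgroupOnly restrict the lipid side to headgroup atoms
#'   (default TRUE, the counting convention for headgroup contacts).
#' @return data.frame with columns `lipid` and `protein` (residue keys),
#'   `lipidResname`, `subunit` (of the protein residue) and `dist` (nm).
#' @export
heavyAtomContacts <- function(frame, system, cutoff = 0.36,
                              headgroupOnly = TRUE) {
  at <- system@atoms
  res <- system@residues
  sp <- res$species[at$residueKey]
  lipSel <- which(sp %in% c("lipid", "sterol") & at$isHeavy &
                    (if (headgroupOnly) headgroupMask(system) else TRUE))
  protSel <- which(sp == "protein" & at$isHeavy)
  if (!length(lipSel) || !length(protSel))
    return(data.frame(lipid = integer(), protein = integer(),
                      lipidResname = character(), subunit = integer(),
                      dist = numeric()))
  hits <- pairWithinCutoff(frame@coords[lipSel, , drop = FALSE],
                           frame@coords[protSel, , drop = FALSE],
                           frame@box, cutoff)
  if (!nrow(hits))
    return(data.frame(lipid = integer(), protein = integer(),
                      lipidResname = character(), subunit = integer(),
                      dist = numeric()))
  lipKey <- at$residueKey[lipSel[hits$i]]
  protKey <- at$residueKey[protSel[hits$j]]
  pair <- paste(lipKey, protKey)
  ord <- order(pair, hits$dist)
  first <- !duplicated(pair[ord])
  sel <- ord[first]
  out <- data.frame(lipid = lipKey[sel], protein = protKey[sel],
                    lipidResname = res$resname[lipKey[sel]],
                    subunit = res$subunit[protKey[sel]],
                    dist = hits$dist[sel])
  out[order(out$lipid, out$protein), , drop = FALSE]
}

#' Contacts over a trajectory
#'
#' Runs [heavyAtomContacts()] on every frame and binds the results with
#' a 0-based `frame` index column and the frame time.
#'
#' @param frames list of [Frame] objects.
#' @inheritParams heavyAtomContacts
#' @return data.frame of per-frame contacts.
#' @export
trajectoryContacts <- function(frames, system, cutoff = 0.36,
                               headgroupOnly = TRUE) {
  out <- lapply(seq_along(frames), function(f) {
    cc <- heavyAtomContacts(frames[[f]], system, cutoff, headgroupOnly)
    if (nrow(cc)) {
      cc$frame <- f - 1L
      cc$time <- frames[[f]]@time
    } else {
      cc$frame <- integer(0)
      cc$time <- numeric(0)
    }
    cc
  })
  do.call(rbind, out)
}

#' Dual-cutoff residence intervals from a distance series
#'
#' A binding interval opens at the first frame where the distance drops
#' to `startCutoff` or below and closes at the first subsequent frame
#' where it exceeds `releaseCutoff` (the dual-cutoff scheme that
#' suppresses rattling-in-a-cage artifacts; with
#' `releaseCutoff == startCutoff` this reduces to single-cutoff
#' segmentation).  Intervals are half-open `[start, end)` in 0-based
#' frames.  Intervals separated by even a single frame above the release
#' cutoff are not merged.
#'
#' @param distances numeric vector of per-frame distances (nm), or a
#'   pairs x frames matrix (rownames identify the pairs).
#' @param startCutoff contact-formation cutoff in nm (default 0.36).
#' @param releaseCutoff contact-release cutoff in nm (default 0.50, must
#'   be >= `startCutoff`).
#' @param dt frame spacing in ns (for the duration column).
#' @return data.frame with columns `pair`, `start`, `end`, `frames`,
#'   `ns`.
#' @export
residenceIntervals <- function(distances, startCutoff = 0.36,
                               releaseCutoff = 0.50, dt = 1) {
  stopifnot(releaseCutoff >= startCutoff)
  one <- function(d, pairName) {
    n <- length(d)
    starts <- integer(0); ends <- integer(0)
    open <- FALSE; s <- NA_integer_
    for (f in seq_len(n)) {
      if (!open) {
        if (d[f] <= startCutoff) { open <- TRUE; s <- f - 1L }
      } else if (d[f] > releaseCutoff) {
        starts <- c(starts, s); ends <- c(ends, f - 1L)
        open <- FALSE
        if (d[f] <= startCutoff) { open <- TRUE; s <- f - 1L }
      }
    }
    if (open) { starts <- c(starts, s); ends <- c(ends, n) }
    if (!length(starts))
      return(data.frame(pair = character(), start = integer(),
                        end = integer(), frames = integer(),
                        ns = numeric()))
    data.frame(pair = pairName, start = starts, end = ends,
               frames = ends - starts, ns = (ends - starts) * dt)
  }
  if (is.matrix(distances)) {
    nm <- rownames(distances)
    if (is.null(nm)) nm <- as.character(seq_len(nrow(distances)))
    do.call(rbind, lapply(seq_len(nrow(distances)), function(r)
      one(distances[r, ], nm[r])))
  } else {
    one(as.numeric(distances), "1")
  }
}

#' Restrict a trajectory to the analysis window
#'
#' Removes the initial `discard` ns (frames with time < `discard`).
#' Contact counting on full trajectories versus duration analysis on the
#' post-equilibration window are both supported by applying (or not
#' applying) this filter.
#'
#' @param frames list of [Frame] objects.
#' @param discard initial window to drop, in ns (default 500).
#' @return filtered list of frames.
#' @export
analysisWindow <- function(frames, discard = 500) {
  Filter(function(fr) fr@time >= discard, frames)
}
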