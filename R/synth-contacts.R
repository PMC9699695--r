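#' Synthetic lipid-protein contact traces from a planted schedule
#'
#' Emulates binding events: a schedule row says that lipid `lipid`
#' approaches protein residue `residue` to `distance` nm during frames
#' `[start, end)` (0-based, half-open), optionally with a mid-event
#' excursion to `excDistance` during `[excStart, excEnd)`.  Outside
#' events every scheduled pair is kept at least 0.8 nm away (the layout
#' guarantees >= 2 nm).  Rows sharing the same lipid and overlapping
#' frames but naming different residues produce simultaneous contacts
#' (bridging); overlapping rows for the same (lipid, residue) pair are
#' an error.
#'
#' Protein residues sit on a 3 nm grid, one heavy bead each, and are
#' split into `nSubunits` contiguous blocks of `residuesPerSubunit`
#' residues.  The generator returns both the geometric frames (so the
#' distance-based contact detector can be exercised) and the exact
#' per-pair distance series implied by the schedule.
#'
#' @param schedule data.frame with columns lipid, residue, start, end,
#'   distance and optionally excStart, excEnd, excDistance.
#' @param nFrames number of frames.
#' @param nSubunits,residuesPerSubunit protein layout.
#' @param nLipids number of lipid residues (>= max scheduled lipid).
#' @param dt frame spacing in ns.
#' @param seed RNG seed (reserved; the construction is deterministic).
#' @return list(system, frames, distances, pairs) where `distances` is a
#'   pairs x frames matrix (rownames "lipid:residue") and `pairs` the
#'   scheduled (lipid, residue) pairs; carries a `groundTruth`
#'   attribute.
#' @export
synthContactTraces <- function(schedule, nFrames, nSubunits = 1L,
                               residuesPerSubunit = 4L, nLipids = NULL,
                               dt = 1, seed = NULL) {
  cols <- c("lipid", "residue", "start", "end", "distance")
  stopifnot(all(cols %in% names(schedule)))
  if (nrow(schedule)) {
    stopifnot(all(schedule$start >= 0), all(schedule$end <= nFrames),
              all(schedule$end > schedule$start))
    ## overlapping events for the same (lipid, residue) pair are invalid
    byPair <- split(schedule, paste(schedule$lipid, schedule$residue))
    for (sub in byPair) {
      if (nrow(sub) < 2L) next
      sub <- sub[order(sub$start), ]
      if (any(sub$start[-1L] < sub$end[-nrow(sub)]))
        stop("overlapping events for lipid ", sub$lipid[1L],
             ", residue ", sub$residue[1L])
    }
  }
  hasExc <- all(c("excStart", "excEnd", "excDistance") %in% names(schedule))
  nRes <- nSubunits * residuesPerSubunit
  if (is.null(nLipids))
    nLipids <- max(1L, if (nrow(schedule)) max(schedule$lipid) else 1L)
  stopifnot(nRes >= if (nrow(schedule)) max(schedule$residue) else 1L)

  spacing <- 3
  box <- c(spacing * (nRes + 2L), spacing * (nLipids + 2L) + 6, 10)
  resHome <- cbind(spacing * seq_len(nRes), 5, 5)
  lipHome <- cbind(spacing * seq_len(nLipids), box[2L] - 3, 5)

  name <- c(rep("BB", nRes), rep("PO4", nLipids))
  resname <- c(rep("GLY", nRes), rep("POPS", nLipids))
  resid <- seq_len(nRes + nLipids)
  chain <- c(sprintf("S%03d", rep(seq_len(nSubunits),
                                  each = residuesPerSubunit)),
             rep("L", nLipids))
  system <- buildSystem(name, resname, resid, chain)
  system <- assignSubunits(system, nSubunits)

  pairKey <- if (nrow(schedule))
    unique(paste(schedule$lipid, schedule$residue, sep = ":")) else
    character(0)
  distances <- matrix(NA_real_, length(pairKey), nFrames,
                      dimnames = list(pairKey, NULL))

  frames <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    f0 <- f - 1L  # 0-based frame index
    rpos <- resHome
    lpos <- lipHome
    active <- if (nrow(schedule))
      schedule[schedule$start <= f0 & f0 < schedule$end, , drop = FALSE] else
      schedule
    if (nrow(active)) {
      for (lip in unique(active$lipid)) {
        rows <- active[active$lipid == lip, , drop = FALSE]
        d <- rows$distance
        if (hasExc) {
          inExc <- !is.na(rows$excStart) & rows$excStart <= f0 &
            f0 < rows$excEnd
          d[inExc] <- rows$excDistance[inExc]
        }
        ctr <- colMeans(resHome[rows$residue, , drop = FALSE])
        lpos[lip, ] <- ctr
        ## move each scheduled residue bead so its distance to the lipid
        ## equals the planted value; directions alternate along +/- x
        dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
        for (m in seq_len(nrow(rows))) {
          dir <- dirs[(m - 1L) %% 4L + 1L, ]
          rpos[rows$residue[m], ] <- ctr + d[m] * dir
        }
      }
    }
    ## record exact distances for every scheduled pair
    if (length(pairKey)) {
      for (p in seq_along(pairKey)) {
        lr <- as.integer(strsplit(pairKey[p], ":")[[1L]])
        distances[p, f] <- sqrt(sum((lpos[lr[1L], ] - rpos[lr[2L], ])^2))
      }
    }
    frames[[f]] <- new("Frame", time = f0 * dt,
                       coords = unname(rbind(rpos, lpos)), box = box)
  }
  out <- list(system = system, frames = frames, distances = distances,
              pairs = pairKey)
  attr(out, "groundTruth") <- list(
    generator = "synth_contact_traces", seed = seed, schedule = schedule,
    nFrames = nFrames, nSubunits = nSubunits,
    residuesPerSubunit = residuesPerSubunit, nLipids = nLipids, dt = dt,
    lipidKeys = nRes + seq_len(nLipids), residueKeys = seq_len(nRes))
  out
}
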