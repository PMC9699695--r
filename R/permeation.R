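#' Membrane slab boundaries from leaflet headgroup planes
#'
#' The membrane slab an ion must traverse for a permeation event:
#' `zLow`/`zHigh` are the mean headgroup reference-atom z of the lower
#' and upper leaflet.  Boundaries are a per-frame quantity; for an
#' analysis window they are usually fixed to the mean over frames (the
#' default in [permeationEvents()] callers) to avoid spurious events
#' under membrane undulation.
#'
#' @param frame a [Frame].
#' @param system a [MolecularSystem] with leaflets assigned (assigned on
#'   the fly from this frame when all labels are `unassigned`).
#' @return list(zLow, zHigh, sdLow, sdHigh).
#' @export
slabBoundaries <- function(frame, system) {
  res <- system@residues
  if (all(res$leaflet[res$species %in% c("lipid", "sterol")] ==
            "unassigned"))
    system <- assignLeaflets(system, frame)
  res <- system@residues
  zref <- referenceZ(system, frame)
  keys <- as.integer(names(zref))
  leaf <- res$leaflet[match(keys, res$key)]
  zIn <- zref[leaf == "inner"]; zOut <- zref[leaf == "outer"]
  if (!length(zIn) || !length(zOut))
    stop("empty leaflet: cannot define slab boundaries")
  lo <- min(mean(zIn), mean(zOut)); hi <- max(mean(zIn), mean(zOut))
  list(zLow = lo, zHigh = hi,
       sdLow = sd(if (mean(zIn) < mean(zOut)) zIn else zOut),
       sdHigh = sd(if (mean(zIn) < mean(zOut)) zOut else zIn))
}

## Unwrap a wrapped 1-D periodic coordinate series: any step larger than
## Lz/2 in magnitude is a periodic image jump.
unwrapZ <- function(z, Lz) {
  if (length(z) < 2L) return(z)
  dz <- diff(z)
  dz <- dz - Lz * round(dz / Lz)
  c(z[1L], z[1L] + cumsum(dz))
}

#' Complete-crossing ion permeation events
#'
#' Counts permeation events with a three-state machine per ion
#' (below / inside / above the slab): an event is recorded only when an
#' ion enters the slab from one side and exits on the other
#' (full-traversal counting -- re-entries from the same side produce
#' nothing, so interfacial dithering cannot inflate the count).  The z
#' series is unwrapped across the periodic boundary first (jump
#' threshold `Lz/2`), so an ion whose path wraps through the box edge
#' mid-traversal is counted exactly once.
#'
#' @param z numeric matrix (ions x frames) of wrapped z coordinates in
#'   nm, or a single numeric vector for one ion.
#' @param boundaries list with `zLow`, `zHigh` (nm), e.g. from
#'   [slabBoundaries()].
#' @param Lz box height in nm.
#' @param species optional character vector of ion species, recycled
#'   over ions.
#' @return list with `events` (data.frame: ion, species, direction,
#'   entryFrame, exitFrame; frames 0-based), `counts` (per species x
#'   direction table) and `cumulative` (data.frame: frame plus one
#'   cumulative count column per species and direction).
#' @export
permeationEvents <- function(z, boundaries, Lz, species = NULL) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (any(!is.finite(z))) {
    bad <- which(!is.finite(z), arr.ind = TRUE)[1L, ]
    stop("non-finite z for ion ", bad[1L], " at frame ", bad[2L] - 1L)
  }
  zLow <- boundaries$zLow; zHigh <- boundaries$zHigh
  stopifnot(zLow < zHigh, Lz > zHigh)
  nIon <- nrow(z); nFrames <- ncol(z)
  if (is.null(species)) species <- rep("ION", nIon)
  species <- rep_len(species, nIon)
  events <- list()
  for (i in seq_len(nIon)) {
    zu <- unwrapZ(z[i, ], Lz)
    ## state from the wrapped coordinate; periodic jumps teleport
    ## between the two water compartments without touching the slab
    zw <- zu %% Lz
    stateOf <- function(v) if (v < zLow) "below" else
      if (v > zHigh) "above" else "inside"
    state <- stateOf(zw[1L])
    entrySide <- NA_character_; entryFrame <- NA_integer_
    for (f in 2:nFrames) {
      newState <- stateOf(zw[f])
      if (newState == state) next
      jump <- abs(zu[f] - zu[f - 1L]) > Lz / 2  # never true after unwrap
      periodic <- abs(z[i, f] - z[i, f - 1L]) > Lz / 2 &&
        state != "inside" && newState != "inside"
      if (state == "inside") {
        if (!is.na(entrySide) &&
            ((entrySide == "below" && newState == "above") ||
             (entrySide == "above" && newState == "below"))) {
          events[[length(events) + 1L]] <- data.frame(
            ion = i, species = species[i],
            direction = if (newState == "above") "up" else "down",
            entryFrame = entryFrame, exitFrame = f - 1L)
        }
        entrySide <- NA_character_
      } else if (newState == "inside") {
        entrySide <- state
        entryFrame <- f - 1L
      } else if (!periodic && !jump) {
        ## direct below<->above step without a periodic wrap: the ion
        ## crossed the whole slab within one frame interval
        events[[length(events) + 1L]] <- data.frame(
          ion = i, species = species[i],
          direction = if (newState == "above") "up" else "down",
          entryFrame = f - 2L, exitFrame = f - 1L)
      }
      state <- newState
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(ion = integer(), species = character(),
               direction = character(), entryFrame = integer(),
               exitFrame = integer())
  counts <- table(factor(ev$species, levels = unique(species)),
                  factor(ev$direction, levels = c("up", "down")))
  cum <- data.frame(frame = seq_len(nFrames) - 1L)
  for (sp in unique(species)) for (dir in c("up", "down")) {
    sel <- ev$species == sp & ev$direction == dir
    cum[[paste(sp, dir, sep = "_")]] <-
      cumsum(tabulate(ev$exitFrame[sel] + 1L, nbins = nFrames))
  }
  list(events = ev, counts = counts, cumulative = cum)
}

#' Water-column continuity through a pore
#'
#' Splits the slab z-range into bins of height `binDz` and asks whether
#' every bin contains at least one water oxygen within `cylinderRadius`
#' of the pore axis.  An interrupted column (one or more empty bins)
#' reports the gaps.
#'
#' @param frame a [Frame] (or an n x 3 coordinate matrix of water
#'   oxygens).
#' @param system a [MolecularSystem]; water oxygens are selected as
#'   heavy atoms of water residues.  Ignored when `frame` is a matrix.
#' @param axisCenter pore axis (x, y) in nm.
#' @param cylinderRadius cylinder radius in nm (0 is degenerate: never
#'   continuous, warned).
#' @param zRange numeric length-2 slab extent (e.g. from
#'   [slabBoundaries()]).
#' @param binDz bin height in nm; default 0.3 (about one water
#'   diameter).
#' @return list(continuous, gaps, binCounts, edges).
#' @export
waterContinuity <- function(frame, system = NULL, axisCenter,
                            cylinderRadius = 1, zRange, binDz = 0.3) {
  stopifnot(length(zRange) == 2L, zRange[1L] < zRange[2L])
  if (cylinderRadius <= 0)
    warning("cylinderRadius <= 0: the column can never be continuous")
  if (is.matrix(frame)) {
    pos <- frame
  } else {
    at <- system@atoms
    sp <- system@residues$species[at$residueKey]
    sel <- which(sp == "water" & at$isHeavy)
    pos <- frame@coords[sel, , drop = FALSE]
  }
  edges <- seq(zRange[1L], zRange[2L], by = binDz)
  if (edges[length(edges)] < zRange[2L]) edges <- c(edges, zRange[2L])
  nb <- length(edges) - 1L
  r <- sqrt((pos[, 1L] - axisCenter[1L])^2 +
              (pos[, 2L] - axisCenter[2L])^2)
  inCyl <- r <= cylinderRadius
  zz <- pos[inCyl, 3L]
  zz <- zz[zz >= edges[1L] & zz <= edges[length(edges)]]
  counts <- if (length(zz))
    tabulate(findInterval(zz, edges, rightmost.closed = TRUE),
             nbins = nb) else integer(nb)
  gaps <- which(counts == 0L)
  list(continuous = length(gaps) == 0L && cylinderRadius > 0,
       gaps = gaps, binCounts = counts, edges = edges)
}
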