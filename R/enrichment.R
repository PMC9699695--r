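#' Per-residue contact occupancy
#'
#' Occupancy of a protein residue by a lipid species: the fraction of
#' analyzed frames in which at least one contact between the two exists.
#' With `bySubunit = TRUE` occupancies are averaged over subunits by the
#' residue's position within its subunit (the reduction used when a
#' homo-oligomer's subunits are equivalent), which requires every
#' subunit to hold the same number of residues.
#'
#' @param contacts data.frame from [trajectoryContacts()] (needs
#'   `frame`, `protein`, `lipidResname` columns).
#' @param system the [MolecularSystem] the contacts refer to.
#' @param nFrames number of analyzed frames (denominator).
#' @param bySubunit average over subunits (default FALSE).
#' @return data.frame with columns `residue` (residue key, or
#'   within-subunit position when averaging), `species`, `occupancy`.
#' @export
contactOccupancy <- function(contacts, system, nFrames,
                             bySubunit = FALSE) {
  stopifnot(nFrames >= 1)
  if (!nrow(contacts))
    return(data.frame(residue = integer(), species = character(),
                      occupancy = numeric()))
  res <- system@residues
  cc <- contacts
  if (bySubunit) {
    protKeys <- res$key[res$species == "protein"]
    subs <- res$subunit[match(protKeys, res$key)]
    if (any(is.na(subs))) stop("subunits not assigned")
    perSub <- table(subs)
    if (length(unique(perSub)) != 1L)
      stop("subunit averaging requires equal-size subunits")
    pos <- stats::ave(seq_along(protKeys), subs, FUN = seq_along)
    cc$unit <- pos[match(cc$protein, protKeys)]
    nUnits <- length(unique(subs))
  } else {
    cc$unit <- cc$protein
    nUnits <- 1L
  }
  key <- paste(cc$unit, cc$lipidResname, cc$frame)
  uniq <- !duplicated(paste(key, if (bySubunit)
    res$subunit[match(cc$protein, res$key)] else 0L))
  cc <- cc[uniq, , drop = FALSE]
  agg <- aggregate(list(hits = rep(1L, nrow(cc))),
                   by = list(residue = cc$unit,
                             species = cc$lipidResname), FUN = sum)
  agg$occupancy <- agg$hits / (nFrames * nUnits)
  agg[order(agg$residue, agg$species), c("residue", "species", "occupancy")]
}

#' Species enrichment of lipid-protein contacts over abundance
#'
#' Enrichment of a lipid species at the protein surface relative to its
#' leaflet abundance: (species share of lipid-protein contact records) /
#' (species mole fraction in the reference leaflet).  A value of 1 means
#' the species contacts the protein exactly as often as expected from
#' its abundance.  Species present in the leaflet but never in contact
#' get enrichment 0; species in contact but absent from the leaflet get
#' NA (undefined) with a note.
#'
#' @param contacts data.frame with a `lipidResname` column (one row per
#'   contact record).
#' @param system the [MolecularSystem]; its leaflet labels supply the
#'   census.
#' @param leaflet reference leaflet ("inner" by default -- the leaflet a
#'   cytosolic pore-former binds).
#' @param moleFractions optional named vector of mole fractions
#'   overriding the system census (e.g. from a composition recipe).
#' @return data.frame with columns `species`, `contactShare`,
#'   `moleFraction`, `enrichment`.
#' @export
speciesEnrichment <- function(contacts, system, leaflet = "inner",
                              moleFractions = NULL) {
  if (is.null(moleFractions)) {
    res <- system@residues
    inLeaf <- res$species %in% c("lipid", "sterol") &
      res$leaflet == leaflet
    if (!any(inLeaf)) stop("no lipids assigned to leaflet '", leaflet, "'")
    census <- table(res$resname[inLeaf])
    moleFractions <- as.numeric(census) / sum(census)
    names(moleFractions) <- names(census)
  }
  total <- nrow(contacts)
  species <- union(names(moleFractions),
                   unique(contacts$lipidResname))
  share <- vapply(species, function(s)
    if (total) sum(contacts$lipidResname == s) / total else 0, numeric(1))
  mf <- moleFractions[species]
  mf[is.na(mf)] <- 0
  enr <- ifelse(mf > 0, share / mf, ifelse(share > 0, NA_real_, 0))
  if (any(is.na(enr)))
    message("species with contacts but zero leaflet abundance: ",
            paste(species[is.na(enr)], collapse = ", "),
            " (enrichment undefined)")
  data.frame(species = species, contactShare = unname(share),
             moleFraction = unname(mf), enrichment = unname(enr),
             row.names = NULL)
}

#' Bridging lipids across adjacent subunit interfaces
#'
#' A lipid is bridging at a frame if it has at least one headgroup
#' heavy-atom contact with each of two adjacent subunits in that frame
#' (the double-sided-tape configuration).  Adjacency means consecutive
#' subunits along the arc, closed into a ring when `closed = TRUE`.
#' Lipids simultaneously contacting two non-adjacent subunits are
#' tallied separately, not as bridges.
#'
#' @param contacts data.frame from [trajectoryContacts()] (columns
#'   `frame`, `lipid`, `subunit`, `lipidResname`).
#' @param nSubunits number of subunits (>= 2).
#' @param nFrames number of frames in the analyzed trajectory.
#' @param closed treat the assembly as a closed ring.
#' @param species optional lipid resname filter (e.g. a PI(4,5)P2
#'   residue name).
#' @return list with `perFrame` (data.frame: frame, bridging,
#'   nonAdjacent), `perInterface` (interfaces x frames count matrix,
#'   rownames "i-j") and `records` (data.frame: frame, lipid, i, j).
#' @export
bridgingLipids <- function(contacts, nSubunits, nFrames, closed = TRUE,
                           species = NULL) {
  if (nSubunits < 2L) stop("bridging requires at least 2 subunits")
  if (!is.null(species))
    contacts <- contacts[contacts$lipidResname %in% species, ,
                         drop = FALSE]
  iFirst <- seq_len(if (closed) nSubunits else nSubunits - 1L)
  iSecond <- iFirst %% nSubunits + 1L
  ifLabels <- paste(iFirst, iSecond, sep = "-")
  perInterface <- matrix(0L, length(ifLabels), nFrames,
                         dimnames = list(ifLabels, NULL))
  perFrame <- data.frame(frame = seq_len(nFrames) - 1L, bridging = 0L,
                         nonAdjacent = 0L)
  recs <- list()
  if (nrow(contacts)) {
    contacts <- contacts[!is.na(contacts$subunit), , drop = FALSE]
    byFrame <- split(contacts, contacts$frame)
    for (cf in byFrame) {
      f <- cf$frame[1L]
      col <- f + 1L
      if (col < 1L || col > nFrames) next
      byLip <- split(cf$subunit, cf$lipid)
      nBridge <- 0L; nNonAdj <- 0L
      for (lip in names(byLip)) {
        subs <- sort(unique(byLip[[lip]]))
        if (length(subs) < 2L) next
        bridged <- FALSE
        for (k in seq_along(iFirst)) {
          if (iFirst[k] %in% subs && iSecond[k] %in% subs) {
            perInterface[k, col] <- perInterface[k, col] + 1L
            recs[[length(recs) + 1L]] <-
              data.frame(frame = f, lipid = as.integer(lip),
                         i = iFirst[k], j = iSecond[k])
            bridged <- TRUE
          }
        }
        if (bridged) nBridge <- nBridge + 1L
        else nNonAdj <- nNonAdj + 1L
      }
      perFrame$bridging[col] <- nBridge
      perFrame$nonAdjacent[col] <- nNonAdj
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(frame = integer(), lipid = integer(), i = integer(),
               j = integer())
  list(perFrame = perFrame, perInterface = perInterface,
       records = records)
}
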