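## Central S4 containers.  A MolecularSystem holds the static description
## (atoms, residues, classifications); coordinates live in Frame objects so
## a single system can be paired with many trajectory frames.

SPECIES_CLASSES <- c("protein", "lipid", "sterol", "water", "ion")
LEAFLET_LABELS <- c("inner", "outer", "unassigned")

#' Frame: per-frame coordinates and box
#'
#' A single trajectory frame: time (ns), an n x 3 coordinate matrix (nm)
#' and orthorhombic box lengths (Lx, Ly, Lz) in nm.
#'
#' @slot time simulation time in ns.
#' @slot coords numeric matrix, one row per atom, columns x, y, z (nm).
#' @slot box numeric length-3 vector of box lengths (nm), all positive.
#' @exportClass Frame
setClass("Frame",
  representation(time = "numeric", coords = "matrix", box = "numeric"))

setValidity("Frame", function(object) {
  msgs <- character()
  if (length(object@time) != 1L || !is.finite(object@time))
    msgs <- c(msgs, "time must be a single finite number (ns)")
  if (ncol(object@coords) != 3L)
    msgs <- c(msgs, "coords must have 3 columns (x, y, z in nm)")
  if (length(object@box) != 3L || any(!is.finite(object@box)) ||
      any(object@box <= 0))
    msgs <- c(msgs, "box must be 3 positive lengths (nm)")
  if (length(msgs)) msgs else TRUE
})

#' MolecularSystem: atoms, residues and their classifications
#'
#' Static description of a simulation system.  `atoms` has one row per
#' atom (name, element, resname, resid, chain, isHeavy, residueKey);
#' `residues` one row per residue (key, resid, resname, chain, species,
#' leaflet, subunit).  `headgroups` maps lipid residue names to the atom
#' names forming the headgroup (entry "default" is the fallback).
#'
#' @slot atoms data.frame of per-atom records.
#' @slot residues data.frame of per-residue records; `species` is one of
#'   protein/lipid/sterol/water/ion, `leaflet` one of
#'   inner/outer/unassigned, `subunit` an integer (NA outside proteins).
#' @slot headgroups named list of character vectors of atom names.
#' @exportClass MolecularSystem
setClass("MolecularSystem",
  representation(atoms = "data.frame", residues = "data.frame",
                 headgroups = "list"))

setValidity("MolecularSystem", function(object) {
  msgs <- character()
  atomCols <- c("name", "element", "resname", "resid", "chain", "isHeavy",
                "residueKey")
  resCols <- c("key", "resid", "resname", "chain", "species", "leaflet",
               "subunit")
  if (!all(atomCols %in% names(object@atoms)))
    msgs <- c(msgs, paste("atoms must have columns:",
                          paste(atomCols, collapse = ", ")))
  if (!all(resCols %in% names(object@residues)))
    msgs <- c(msgs, paste("residues must have columns:",
                          paste(resCols, collapse = ", ")))
  if (!length(msgs)) {
    if (nrow(object@atoms) &&
        any(object@atoms$resid < 0, na.rm = TRUE))
      msgs <- c(msgs, "residue ids must be >= 0")
    if (nrow(object@atoms) &&
        !all(object@atoms$isHeavy == (object@atoms$element != "H")))
      msgs <- c(msgs, "isHeavy must equal (element != 'H')")
    if (nrow(object@residues) &&
        !all(object@residues$species %in% SPECIES_CLASSES))
      msgs <- c(msgs, paste("species must be one of",
                            paste(SPECIES_CLASSES, collapse = "/")))
    if (nrow(object@residues) &&
        !all(object@residues$leaflet %in% LEAFLET_LABELS))
      msgs <- c(msgs, paste("leaflet must be one of",
                            paste(LEAFLET_LABELS, collapse = "/")))
    if (nrow(object@atoms) &&
        (any(object@atoms$residueKey < 1L) ||
         any(object@atoms$residueKey > nrow(object@residues))))
      msgs <- c(msgs, "residueKey out of range")
  }
  if (length(msgs)) msgs else TRUE
})

#' PressureBoxSeries: pressure-tensor and box time series
#'
#' Time series of the diagonal pressure-tensor elements (bar) and lateral
#' box lengths (nm), the inputs of the edge-tension estimator.
#'
#' @slot time times in ns.
#' @slot Pxx,Pyy,Pzz diagonal pressure components in bar.
#' @slot Lx,Ly box lengths in nm (positive).
#' @exportClass PressureBoxSeries
setClass("PressureBoxSeries",
  representation(time = "numeric", Pxx = "numeric", Pyy = "numeric",
                 Pzz = "numeric", Lx = "numeric", Ly = "numeric"))

setValidity("PressureBoxSeries", function(object) {
  n <- length(object@time)
  lens <- c(length(object@Pxx), length(object@Pyy), length(object@Pzz),
            length(object@Lx), length(object@Ly))
  msgs <- character()
  if (any(lens != n))
    msgs <- c(msgs, "all series must have equal length")
  if (n && (any(object@Lx <= 0) || any(object@Ly <= 0)))
    msgs <- c(msgs, "Lx and Ly must be positive")
  if (length(msgs)) msgs else TRUE
})

#' EdgeTensionResult: estimate of membrane edge tension
#'
#' @slot gamma edge tension in pN.
#' @slot sem block-averaged standard error in pN (NA if < 2 blocks).
#' @slot nEdges number of open edges the estimate is normalized by.
#' @slot nBlocks number of non-overlapping blocks used for the SEM.
#' @slot discarded length of the discarded initial window in ns.
#' @exportClass EdgeTensionResult
setClass("EdgeTensionResult",
  representation(gamma = "numeric", sem = "numeric", nEdges = "integer",
                 nBlocks = "integer", discarded = "numeric"))

setValidity("EdgeTensionResult", function(object) {
  msgs <- character()
  if (object@nEdges < 1L) msgs <- c(msgs, "nEdges must be >= 1")
  if (!is.na(object@sem) && object@sem < 0)
    msgs <- c(msgs, "sem must be >= 0")
  if (length(msgs)) msgs else TRUE
})
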