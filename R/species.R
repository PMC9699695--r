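## Residue-name -> species dictionaries and headgroup atom tables.
## GRO files carry no element field, so elements are inferred from atom
## names (first alphabetic character) with an exception table for ions.

PROTEIN_RESNAMES <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "HSD",
  "HSE", "HSP", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR",
  "TRP", "TYR", "VAL",
  ## pseudo-residues used by the synthetic ring generator
  "GLB", "HPB", "HPT")

WATER_RESNAMES <- c("SOL", "TIP3", "TIP", "HOH", "WAT", "W")
ION_RESNAMES <- c("NA", "NA+", "SOD", "CL", "CL-", "CLA", "K", "K+",
                  "POT", "MG", "CA", "CAL")
STEROL_RESNAMES <- c("CHOL", "CHL1", "ERG", "CHMS")

#' Default residue-name to species dictionary
#'
#' Maps residue names to one of protein/lipid/sterol/water/ion.  Residue
#' names absent from the dictionary are classified as `lipid` (the
#' membrane-centric default) -- supply your own mapping to override.
#'
#' @return named character vector (resname -> species class).
#' @export
defaultSpeciesMap <- function() {
  c(setNames(rep("protein", length(PROTEIN_RESNAMES)), PROTEIN_RESNAMES),
    setNames(rep("water", length(WATER_RESNAMES)), WATER_RESNAMES),
    setNames(rep("ion", length(ION_RESNAMES)), ION_RESNAMES),
    setNames(rep("sterol", length(STEROL_RESNAMES)), STEROL_RESNAMES))
}

#' Default headgroup atom-name table
#'
#' Atom names considered part of a lipid headgroup, per residue name,
#' with a `"default"` fallback for unlisted phospholipids (phosphate
#' phosphorus and its linked polar atoms).  For PI(4,5)P2 the inositol
#' ring and both ring phosphates are included; for sterols the hydroxyl
#' group.  Override by passing a modified list to the readers/analyses.
#'
#' @return named list of character vectors of atom names.
#' @export
defaultHeadgroupTable <- function() {
  phosGlycerol <- c("P", "PO4", "O11", "O12", "O13", "O14",
                    "N", "C11", "C12", "C13", "C14", "C15")
  pip2 <- c(phosGlycerol, "P4", "P5",
            paste0("OP", 42:44), paste0("OP", 52:54),
            paste0("C", 1:6), paste0("O", 2:6))
  sterol <- c("O3", "OH", "ROH", "O1")
  list(default = phosGlycerol,
       POPI24 = pip2, PIP2 = pip2, SAPI24 = pip2, PLPI24 = pip2,
       CHOL = sterol, CHL1 = sterol, ERG = sterol)
}

## Headgroup reference atom (defines a lipid's z for leaflet bookkeeping):
## phosphorus for phospholipids, hydroxyl oxygen for sterols.  Configurable
## because the choice is a convention, not data.
defaultReferenceAtoms <- function() {
  list(lipid = c("P", "PO4", "P8"), sterol = c("O3", "OH", "ROH", "O1"))
}

#' Infer element symbols from atom names
#'
#' First alphabetic character of the atom name, with an exception table
#' for two-letter ion/halide names (CL, NA, MG, CA in ion residues) and
#' coarse pseudo-atom beads.
#'
#' @param names character vector of atom names.
#' @param resnames optional residue names of the same length (used to
#'   disambiguate CL/NA as ions).
#' @return character vector of element symbols.
#' @export
inferElements <- function(names, resnames = NULL) {
  out <- character(length(names))
  stripped <- gsub("^[^A-Za-z]+", "", names)
  first <- toupper(substr(stripped, 1L, 1L))
  out <- first
  ## pseudo-atom beads used by the synthetic generators are "carbon-like"
  out[stripped %in% c("PO4", "ROH", "BB", "BAS", "TIP", "GLB")] <- "C"
  out[stripped == "PO4"] <- "P"
  out[stripped == "ROH"] <- "O"
  if (!is.null(resnames)) {
    ionic <- toupper(resnames) %in% ION_RESNAMES
    two <- toupper(substr(stripped, 1L, 2L))
    out[ionic & two == "CL"] <- "Cl"
    out[ionic & two %in% c("NA", "SO")] <- "Na"
    out[ionic & two %in% c("K", "PO")] <- "K"
    out[ionic & two %in% c("MG")] <- "Mg"
    out[ionic & two %in% c("CA")] <- "Ca"
  }
  out
}

## Assemble a MolecularSystem from raw per-atom vectors.  Residues are
## delimited by changes in (chain, resid, resname) in file order, matching
## GRO/PDB conventions.
buildSystem <- function(name, resname, resid, chain = NULL,
                        speciesMap = defaultSpeciesMap(),
                        headgroupTable = defaultHeadgroupTable()) {
  n <- length(name)
  if (n == 0L) {
    empty <- data.frame(name = character(), element = character(),
                        resname = character(), resid = integer(),
                        chain = character(), isHeavy = logical(),
                        residueKey = integer(), stringsAsFactors = FALSE)
    emptyRes <- data.frame(key = integer(), resid = integer(),
                           resname = character(), chain = character(),
                           species = character(), leaflet = character(),
                           subunit = integer(), stringsAsFactors = FALSE)
    return(new("MolecularSystem", atoms = empty, residues = emptyRes,
               headgroups = headgroupTable))
  }
  if (is.null(chain)) chain <- rep("A", n)
  element <- inferElements(name, resname)
  resBreak <- c(TRUE, resid[-1L] != resid[-n] |
                  resname[-1L] != resname[-n] | chain[-1L] != chain[-n])
  residueKey <- cumsum(resBreak)
  idx <- which(resBreak)
  rn <- toupper(resname[idx])
  species <- unname(speciesMap[rn])
  species[is.na(species)] <- "lipid"
  atomsDf <- data.frame(
    name = name, element = element, resname = resname,
    resid = as.integer(resid), chain = chain,
    isHeavy = element != "H", residueKey = as.integer(residueKey),
    stringsAsFactors = FALSE)
  residuesDf <- data.frame(
    key = seq_along(idx), resid = as.integer(resid[idx]),
    resname = resname[idx], chain = chain[idx], species = species,
    leaflet = "unassigned", subunit = NA_integer_,
    stringsAsFactors = FALSE)
  new("MolecularSystem", atoms = atomsDf, residues = residuesDf,
      headgroups = headgroupTable)
}

## Logical mask: is atom i part of its residue's headgroup?  Only
## meaningful for lipid/sterol residues.
headgroupMask <- function(system) {
  at <- system@atoms
  res <- system@residues
  sp <- res$species[at$residueKey]
  tab <- system@headgroups
  sets <- lapply(toupper(at$resname), function(rn)
    if (!is.null(tab[[rn]])) tab[[rn]] else tab[["default"]])
  inSet <- mapply(function(nm, s) nm %in% s, at$name, sets,
                  USE.NAMES = FALSE)
  inSet & sp %in% c("lipid", "sterol")
}

## z of the headgroup reference atom for each lipid/sterol residue; falls
## back to the mean headgroup z, then the residue mean z.
referenceZ <- function(system, frame, refAtoms = defaultReferenceAtoms()) {
  at <- system@atoms
  res <- system@residues
  z <- frame@coords[, 3L]
  lipKeys <- res$key[res$species %in% c("lipid", "sterol")]
  hm <- headgroupMask(system)
  vapply(lipKeys, function(k) {
    rows <- which(at$residueKey == k)
    sp <- res$species[k]
    wanted <- refAtoms[[if (sp == "sterol") "sterol" else "lipid"]]
    hit <- rows[at$name[rows] %in% wanted]
    if (length(hit)) return(mean(z[hit]))
    hg <- rows[hm[rows]]
    if (length(hg)) mean(z[hg]) else mean(z[rows])
  }, numeric(1L)) -> zref
  setNames(zref, lipKeys)
}
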