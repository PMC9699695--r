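#' Assign lipids to membrane leaflets
#'
#' Labels every lipid/sterol residue `inner` or `outer` by the sign of
#' its headgroup reference-atom z relative to the membrane midplane (the
#' mean reference z over all lipids).  The cytosolic (inner) leaflet is
#' taken as the side below the midplane.  For sterols the hydroxyl
#' oxygen is the reference; for phospholipids the phosphorus.  The
#' assignment is invariant under rigid z-translation because the
#' midplane moves with the system.
#'
#' @param system a [MolecularSystem].
#' @param frame a [Frame].
#' @param refAtoms reference-atom name table (see package defaults).
#' @return the system with per-residue `leaflet` labels filled in.
#' @export
assignLeaflets <- function(system, frame,
                           refAtoms = defaultReferenceAtoms()) {
  res <- system@residues
  isLip <- res$species %in% c("lipid", "sterol")
  if (!any(isLip)) stop("no lipids in system; cannot assign leaflets")
  zref <- referenceZ(system, frame, refAtoms)
  mid <- mean(zref)
  lab <- ifelse(zref < mid, "inner", "outer")
  if (diff(range(zref)) < 1) {
    warning("lipid reference atoms span < 1 nm in z; ",
            "membrane appears single-leafleted, labelling all 'outer'")
    lab[] <- "outer"
  }
  res$leaflet[isLip] <- lab[match(res$key[isLip], as.integer(names(zref)))]
  system@residues <- res
  validObject(system)
  system
}

#' Assign protein residues to subunits
#'
#' Uses chain identifiers when more than one chain is present among
#' protein residues; otherwise splits the protein residues into
#' `nSubunits` equal contiguous blocks (in order).  Subunit labels are
#' 1-based and form a disjoint cover of the protein residues.
#'
#' @param system a [MolecularSystem].
#' @param nSubunits number of subunits (ignored when chains decide).
#' @return the system with per-residue `subunit` indices filled in.
#' @export
assignSubunits <- function(system, nSubunits = NULL) {
  res <- system@residues
  isProt <- res$species == "protein"
  if (!any(isProt)) stop("no protein residues in system")
  chains <- res$chain[isProt]
  uc <- unique(chains)
  if (length(uc) > 1L) {
    sub <- match(chains, uc)
  } else {
    if (is.null(nSubunits))
      stop("single chain and no nSubunits given")
    nProt <- sum(isProt)
    if (nProt %% nSubunits != 0L)
      stop(nProt, " protein residues not divisible by ", nSubunits,
           " subunits and no chain identifiers present")
    sub <- rep(seq_len(nSubunits), each = nProt %/% nSubunits)
  }
  res$subunit[isProt] <- as.integer(sub)
  system@residues <- res
  validObject(system)
  system
}
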