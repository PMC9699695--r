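#' Accessors for poremetrics S4 containers
#'
#' Standard accessors: `nAtoms()`/`nResidues()` count atoms/residues,
#' `atoms()`/`residues()` return the underlying data.frames, `coords()`,
#' `boxDims()` and `frameTime()` extract a [Frame]'s coordinate matrix,
#' box lengths and time, `leaflets()` and `subunits()` return (and their
#' replacement forms set) per-residue leaflet labels and subunit indices,
#' `headgroups()` the headgroup atom-name table, and `tension()`/
#' `tensionSEM()` the estimate held by an [EdgeTensionResult].
#'
#' @param x a poremetrics object.
#' @param value replacement value (per-residue vector).
#' @name accessors
NULL

#' @rdname accessors
setMethod("nAtoms", "MolecularSystem", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("nAtoms", "Frame", function(x) nrow(x@coords))

#' @rdname accessors
setMethod("nResidues", "MolecularSystem", function(x) nrow(x@residues))

#' @rdname accessors
setMethod("atoms", "MolecularSystem", function(x) x@atoms)

#' @rdname accessors
setMethod("residues", "MolecularSystem", function(x) x@residues)

#' @rdname accessors
setMethod("coords", "Frame", function(x) x@coords)

#' @rdname accessors
setMethod("boxDims", "Frame", function(x) x@box)

#' @rdname accessors
setMethod("frameTime", "Frame", function(x) x@time)

#' @rdname accessors
setMethod("leaflets", "MolecularSystem", function(x)
  setNames(x@residues$leaflet, x@residues$key))

#' @rdname accessors
setMethod("leaflets<-", "MolecularSystem", function(x, value) {
  stopifnot(length(value) == nrow(x@residues))
  x@residues$leaflet <- as.character(value)
  validObject(x)
  x
})

#' @rdname accessors
setMethod("subunits", "MolecularSystem", function(x)
  setNames(x@residues$subunit, x@residues$key))

#' @rdname accessors
setMethod("subunits<-", "MolecularSystem", function(x, value) {
  stopifnot(length(value) == nrow(x@residues))
  x@residues$subunit <- as.integer(value)
  validObject(x)
  x
})

#' @rdname accessors
setMethod("headgroups", "MolecularSystem", function(x) x@headgroups)

#' @rdname accessors
setMethod("tension", "EdgeTensionResult", function(x) x@gamma)

#' @rdname accessors
setMethod("tensionSEM", "EdgeTensionResult", function(x) x@sem)

setMethod("show", "MolecularSystem", function(object) {
  sp <- table(object@residues$species)
  cat("MolecularSystem with", nrow(object@atoms), "atoms in",
      nrow(object@residues), "residues\n")
  cat("  species:", paste(names(sp), sp, sep = ":", collapse = " "), "\n")
  lf <- table(object@residues$leaflet[
    object@residues$species %in% c("lipid", "sterol")])
  if (length(lf))
    cat("  leaflets:", paste(names(lf), lf, sep = ":", collapse = " "), "\n")
  ns <- sum(!is.na(unique(object@residues$subunit)))
  if (ns > 0) cat("  subunits:", ns, "\n")
})

setMethod("show", "Frame", function(object) {
  cat(sprintf("Frame t = %g ns, %d atoms, box %.3f x %.3f x %.3f nm\n",
              object@time, nrow(object@coords),
              object@box[1], object@box[2], object@box[3]))
})

setMethod("show", "PressureBoxSeries", function(object) {
  n <- length(object@time)
  cat("PressureBoxSeries with", n, "frames")
  if (n) cat(sprintf(" spanning %g..%g ns", min(object@time),
                     max(object@time)))
  cat("\n")
})

setMethod("show", "EdgeTensionResult", function(object) {
  cat(sprintf(
    "Edge tension: %.2f pN (SEM %s, %d edges, %d blocks, %g ns discarded)\n",
    object@gamma,
    if (is.na(object@sem)) "n/a" else sprintf("%.2f pN", object@sem),
    object@nEdges, object@nBlocks, object@discarded))
})

#' Ground truth recorded by a synthetic-system generator
#'
#' Every generator attaches a `groundTruth` attribute (generator name,
#' seed, planted parameters) to its output; this accessor retrieves it.
#'
#' @param x an object produced by a `synth*()` generator.
#' @return a list, or NULL when `x` carries no ground truth.
#' @export
groundTruth <- function(x) attr(x, "groundTruth", exact = TRUE)
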