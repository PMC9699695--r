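#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("boxDims", function(x) standardGeneric("boxDims"))

#' @rdname accessors
#' @export
setGeneric("frameTime", function(x) standardGeneric("frameTime"))

#' @rdname accessors
#' @export
setGeneric("leaflets", function(x) standardGeneric("leaflets"))

#' @rdname accessors
#' @export
setGeneric("leaflets<-", function(x, value) standardGeneric("leaflets<-"))

#' @rdname accessors
#' @export
setGeneric("subunits", function(x) standardGeneric("subunits"))

#' @rdname accessors
#' @export
setGeneric("subunits<-", function(x, value) standardGeneric("subunits<-"))

#' @rdname accessors
#' @export
setGeneric("headgroups", function(x) standardGeneric("headgroups"))

#' @rdname accessors
#' @export
setGeneric("tension", function(x) standardGeneric("tension"))

#' @rdname accessors
#' @export
setGeneric("tensionSEM", function(x) standardGeneric("tensionSEM"))
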