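# Accessor generics and methods. Slot access stays internal; user code
# goes through these.

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("proteinId", function(x) standardGeneric("proteinId"))

#' @rdname accessors
#' @export
setGeneric("aaSequence", function(x) standardGeneric("aaSequence"))

#' @rdname accessors
#' @export
setGeneric("ddgValues", function(x) standardGeneric("ddgValues"))

#' @rdname accessors
#' @export
setGeneric("wildtypeMask", function(x) standardGeneric("wildtypeMask"))

#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @rdname accessors
#' @export
setGeneric("cdsSequence", function(x) standardGeneric("cdsSequence"))

#' @rdname accessors
#' @export
setGeneric("confidenceValues", function(x) standardGeneric("confidenceValues"))

#' @rdname accessors
#' @export
setGeneric("sourceKind", function(x) standardGeneric("sourceKind"))

#' @rdname accessors
#' @export
setGeneric("ihsValue", function(x) standardGeneric("ihsValue"))

#' @rdname accessors
#' @export
setGeneric("nQualifying", function(x) standardGeneric("nQualifying"))

#' @rdname accessors
#' @export
setGeneric("calibrationK", function(x) standardGeneric("calibrationK"))

#' Accessors for dosconstraint classes
#'
#' `proteinId()`, `aaSequence()`, `ddgValues()` and `wildtypeMask()` read a
#' [DdgMatrix-class]; `geneId()` and `cdsSequence()` read a
#' [GeneModel-class]; `confidenceValues()`, `sourceKind()` and
#' `proteinId()` read a [StructureConfidence-class]; `ihsValue()` and
#' `nQualifying()` read an [InstabilityHeatScore-class]; `calibrationK()`
#' reads a [CalibrationFactor-class].
#'
#' `wildtypeMask()` returns an L x 20 logical matrix that is `TRUE` at the
#' wild-type residue cell of each position (all `FALSE` on rows whose
#' residue is unknown).
#'
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
setMethod("proteinId", "DdgMatrix", function(x) x@proteinId)

#' @rdname accessors
setMethod("aaSequence", "DdgMatrix", function(x) x@aaSequence)

#' @rdname accessors
setMethod("ddgValues", "DdgMatrix", function(x) x@ddg)

#' @rdname accessors
setMethod("wildtypeMask", "DdgMatrix", function(x) {
  aa <- .chars(x@aaSequence)
  mask <- matrix(FALSE, nrow = nrow(x@ddg), ncol = 20L,
                 dimnames = list(NULL, AA_ALPHABET))
  known <- which(aa %in% AA_ALPHABET)
  mask[cbind(known, match(aa[known], AA_ALPHABET))] <- TRUE
  mask
})

#' @rdname accessors
setMethod("geneId", "GeneModel", function(x) x@geneId)

#' @rdname accessors
setMethod("cdsSequence", "GeneModel", function(x) x@cds)

#' @rdname accessors
setMethod("proteinId", "StructureConfidence", function(x) x@proteinId)

#' @rdname accessors
setMethod("confidenceValues", "StructureConfidence", function(x) {
  setNames(x@values, x@residueIndex)
})

#' @rdname accessors
setMethod("sourceKind", "StructureConfidence", function(x) x@sourceKind)

#' @rdname accessors
setMethod("ihsValue", "InstabilityHeatScore", function(x) x@value)

#' @rdname accessors
setMethod("nQualifying", "InstabilityHeatScore", function(x) x@nQualifying)

#' @rdname accessors
setMethod("calibrationK", "CalibrationFactor", function(x) x@k)
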