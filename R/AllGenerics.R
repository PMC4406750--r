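#' @rdname megSet
#' @export
setGeneric("megSet", function(x, minEvidence = 2L) standardGeneric("megSet"))

#' @rdname vennCounts
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' @rdname evidenceTable
#' @export
setGeneric("evidenceTable", function(x) standardGeneric("evidenceTable"))

#' @rdname permutationAccessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname permutationAccessors
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' @rdname permutationAccessors
#' @export
setGeneric("observedOverlap", function(x) standardGeneric("observedOverlap"))

#' @rdname assayBackground
#' @export
setGeneric("backgroundGenes", function(x) standardGeneric("backgroundGenes"))

#' @rdname assayBackground
#' @export
setGeneric("drawSize", function(x) standardGeneric("drawSize"))
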