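#' @importFrom BiocGenerics sizeFactors sizeFactors<-
NULL

#' Accessors for senescreen classes
#'
#' Small accessor family: `genes()` returns the member genes of a
#' [GeneSet-class]; `tf()` and `targets()` the components of a
#' [Regulon-class]; `stages()`, `rootStages()` and `graphEdges()` the parts
#' of a [TransitionGraph-class]; `tValues()`/`pAdjusted()` the statistic
#' matrices of a [TransitionTable-class]. `sizeFactors()` on a
#' [PseudobulkTable-class] reads/writes `colData(x)$size_factor`.
#'
#' @param x object to access.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setMethod("genes", "GeneSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("tf", function(x) standardGeneric("tf"))
#' @rdname accessors
#' @export
setMethod("tf", "Regulon", function(x) x@tf)

#' @rdname accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))
#' @rdname accessors
#' @export
setMethod("targets", "Regulon", function(x) x@targets)

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname accessors
#' @export
setMethod("stages", "TransitionGraph", function(x) x@stages)

#' @rdname accessors
#' @export
setGeneric("rootStages", function(x) standardGeneric("rootStages"))
#' @rdname accessors
#' @export
setMethod("rootStages", "TransitionGraph", function(x) x@roots)

#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setMethod("graphEdges", "TransitionGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("tValues", function(x) standardGeneric("tValues"))
#' @rdname accessors
#' @export
setMethod("tValues", "TransitionTable", function(x) x@tValues)

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setMethod("pValues", "TransitionTable", function(x) x@pValues)

#' @rdname accessors
#' @export
setGeneric("pAdjusted", function(x) standardGeneric("pAdjusted"))
#' @rdname accessors
#' @export
setMethod("pAdjusted", "TransitionTable", function(x) x@pAdjusted)

#' @rdname accessors
#' @export
setMethod("sizeFactors", "PseudobulkTable", function(object) {
    colData(object)$size_factor
})

#' @rdname accessors
#' @param object a [PseudobulkTable-class].
#' @param value positive numeric vector, one per pseudobulk unit.
#' @export
setMethod("sizeFactors<-", "PseudobulkTable", function(object, ..., value) {
    stopifnot(length(value) == ncol(object), all(value > 0))
    colData(object)$size_factor <- as.numeric(value)
    methods::validObject(object)
    object
})
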