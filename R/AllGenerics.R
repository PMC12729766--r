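#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname accessors
#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))

#' @rdname accessors
#' @export
setGeneric("degradationParams", function(x) standardGeneric("degradationParams"))

#' @rdname accessors
#' @export
setGeneric("biasFactorsOf", function(x) standardGeneric("biasFactorsOf"))

#' @rdname degrade
#' @export
setGeneric("degrade", function(x, params) standardGeneric("degrade"))

#' @rdname repairExpression
#' @export
setGeneric("repairExpression", function(model, x) standardGeneric("repairExpression"))
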