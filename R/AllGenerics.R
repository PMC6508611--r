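#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("healthyControl", function(x) standardGeneric("healthyControl"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("diseaseControl", function(x) standardGeneric("diseaseControl"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("treatmentArms", function(x) standardGeneric("treatmentArms"))

#' @rdname ExpressionStudy-accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))

#' @rdname deGenes
#' @export
setGeneric("deGenes", function(x, condition = NULL, ...)
    standardGeneric("deGenes"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname AnnotationSet-accessors
#' @export
setGeneric("categoryIds", function(x) standardGeneric("categoryIds"))
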