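#' @rdname PathwayGraph-class
#' @param object,x an object of the documented class
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("nodeTable", function(object) standardGeneric("nodeTable"))

#' @rdname PathwayGraph-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname Circuit-class
#' @param object,x an object of the documented class
#' @export
setGeneric("circuitId", function(object) standardGeneric("circuitId"))

#' @rdname Circuit-class
#' @export
setGeneric("effector", function(object) standardGeneric("effector"))

#' @rdname Circuit-class
#' @export
setGeneric("receptors", function(object) standardGeneric("receptors"))

#' @rdname Circuit-class
#' @export
setGeneric("memberNodes", function(object) standardGeneric("memberNodes"))

#' @rdname Circuit-class
#' @export
setGeneric("memberEdges", function(object) standardGeneric("memberEdges"))

#' @rdname Circuit-class
#' @export
setGeneric("displayName", function(object) standardGeneric("displayName"))

#' @rdname GeneExpressionMatrix-class
#' @param object,x an object of the documented class
#' @export
setGeneric("scaleType", function(object) standardGeneric("scaleType"))

#' @rdname NodeValueMatrix-class
#' @param object,x an object of the documented class
#' @export
setGeneric("flaggedNodes", function(object) standardGeneric("flaggedNodes"))

#' @rdname CircuitActivityMatrix-class
#' @param object,x an object of the documented class
#' @export
setGeneric("convergenceReport",
           function(object) standardGeneric("convergenceReport"))

#' @rdname DrugSpec-class
#' @param object an object of the documented class
#' @export
setGeneric("drugName", function(object) standardGeneric("drugName"))

#' @rdname DrugSpec-class
#' @export
setGeneric("drugTargets", function(object) standardGeneric("drugTargets"))

#' @rdname DrugSpec-class
#' @export
setGeneric("knockdownValue",
           function(object) standardGeneric("knockdownValue"))

#' @rdname FoldChangeMatrix-class
#' @param object an object of the documented class
#' @export
setGeneric("foldChanges", function(object) standardGeneric("foldChanges"))

#' @rdname SyntheticScenario-class
#' @param object an object of the documented class
#' @export
setGeneric("scenarioTruth", function(object) standardGeneric("scenarioTruth"))
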