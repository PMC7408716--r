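#' @rdname PathwayGraph-class
#' @aliases pathwayId,PathwayGraph-method
setMethod("pathwayId", "PathwayGraph", function(object) object@pathwayId)

#' @rdname PathwayGraph-class
setMethod("nodeTable", "PathwayGraph", function(object) object@nodes)

#' @rdname PathwayGraph-class
setMethod("edgeTable", "PathwayGraph", function(object) object@edges)

#' @rdname Circuit-class
setMethod("circuitId", "Circuit", function(object) object@circuitId)

#' @rdname Circuit-class
setMethod("pathwayId", "Circuit", function(object) object@pathwayId)

#' @rdname Circuit-class
setMethod("effector", "Circuit", function(object) object@effector)

#' @rdname Circuit-class
setMethod("receptors", "Circuit", function(object) object@receptors)

#' @rdname Circuit-class
setMethod("memberNodes", "Circuit", function(object) object@memberNodes)

#' @rdname Circuit-class
setMethod("memberEdges", "Circuit", function(object) object@memberEdges)

#' @rdname Circuit-class
setMethod("displayName", "Circuit", function(object) object@displayName)

#' @rdname GeneExpressionMatrix-class
setMethod("scaleType", "GeneExpressionMatrix", function(object) object@scale)

#' @rdname GeneExpressionMatrix-class
#' @param ... unused
#' @export
setMethod("as.matrix", "GeneExpressionMatrix", function(x, ...) x@values)

#' @rdname GeneExpressionMatrix-class
#' @export
setMethod("dim", "GeneExpressionMatrix", function(x) dim(x@values))

#' @rdname NodeValueMatrix-class
#' @param ... unused
#' @export
setMethod("as.matrix", "NodeValueMatrix", function(x, ...) x@values)

#' @rdname NodeValueMatrix-class
setMethod("flaggedNodes", "NodeValueMatrix", function(object) object@flags)

#' @rdname CircuitActivityMatrix-class
#' @param ... unused
#' @export
setMethod("as.matrix", "CircuitActivityMatrix", function(x, ...) x@activity)

#' @rdname CircuitActivityMatrix-class
#' @export
setMethod("dim", "CircuitActivityMatrix", function(x) dim(x@activity))

#' @rdname CircuitActivityMatrix-class
setMethod("convergenceReport", "CircuitActivityMatrix",
          function(object) object@report)

#' @rdname DrugSpec-class
setMethod("drugName", "DrugSpec", function(object) object@drugName)

#' @rdname DrugSpec-class
setMethod("drugTargets", "DrugSpec", function(object) object@targets)

#' @rdname DrugSpec-class
setMethod("knockdownValue", "DrugSpec", function(object) object@knockdownValue)

#' @rdname FoldChangeMatrix-class
setMethod("foldChanges", "FoldChangeMatrix", function(object) object@fc)

#' @rdname SyntheticScenario-class
setMethod("scenarioTruth", "SyntheticScenario", function(object) {
  list(gsdsa = object@truthGsdsa, null = object@truthNull,
       deCircuits = object@deCircuits)
})

setMethod("show", "PathwayGraph", function(object) {
  cat("PathwayGraph '", object@pathwayId, "': ",
      nrow(object@nodes), " nodes, ", nrow(object@edges), " edges (",
      sum(object@edges$sign == "inhibition"), " inhibitory)\n", sep = "")
})

setMethod("show", "Circuit", function(object) {
  cat("Circuit ", object@circuitId, " ('", object@displayName, "')\n",
      "  effector: ", object@effector,
      "; receptors: ", paste(object@receptors, collapse = ", "), "\n",
      "  ", length(object@memberNodes), " member nodes, ",
      nrow(object@memberEdges), " member edges\n", sep = "")
})

setMethod("show", "GeneExpressionMatrix", function(object) {
  cat("GeneExpressionMatrix: ", nrow(object@values), " genes x ",
      ncol(object@values), " samples [scale: ", object@scale, "]\n", sep = "")
})

setMethod("show", "NodeValueMatrix", function(object) {
  cat("NodeValueMatrix: ", nrow(object@values), " nodes x ",
      ncol(object@values), " samples; ", nrow(object@flags),
      " node(s) at neutral value\n", sep = "")
})

setMethod("show", "CircuitActivityMatrix", function(object) {
  cat("CircuitActivityMatrix: ", nrow(object@activity), " circuits x ",
      ncol(object@activity), " samples; ",
      sum(!object@report$converged), " non-converged, ",
      sum(object@report$starved), " activation-starved\n", sep = "")
})

setMethod("show", "DrugSpec", function(object) {
  cat("DrugSpec '", object@drugName, "': targets ",
      paste(object@targets, collapse = ", "),
      " (knockdown value ", format(object@knockdownValue), ")\n", sep = "")
})

setMethod("show", "FoldChangeMatrix", function(object) {
  cat("FoldChangeMatrix: ", nrow(object@fc), " circuits x ",
      ncol(object@fc), " samples (epsilon ", format(object@epsilon),
      ")\n", sep = "")
})

setMethod("show", "PropagationState", function(object) {
  cat("PropagationState for ", object@circuit@circuitId,
      ": effector signal ",
      format(object@nodeSignal[object@circuit@effector]),
      if (object@starved) " [activation-starved]" else "",
      if (!object@converged) " [NOT converged]" else "",
      " (", object@iterations, " iteration(s))\n", sep = "")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario (seed ", object@seed, "): ",
      length(object@graphs), " pathways, ",
      nrow(object@expression@values), " genes x ",
      ncol(object@expression@values), " samples (groups: ",
      paste(levels(object@labels), collapse = "/"), ")\n",
      "  truth: ", length(object@truthGsdsa), " differential, ",
      length(object@truthNull), " null circuit(s); ",
      length(object@drugs), " drug(s)\n", sep = "")
})
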