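#' @import methods
NULL

#' Signed directed pathway graph
#'
#' A pathway is a signed directed graph whose nodes represent proteins (or
#' protein complexes, or metabolites) and whose edges carry an activation or
#' inhibition sign.  Each node holds an ordered list of gene symbols; a node
#' with zero genes is permitted (a pseudo-node such as a metabolite) and is
#' treated as gene-free downstream.
#'
#' @slot pathwayId single pathway identifier.
#' @slot nodes data.frame with columns \code{node_id}, \code{genes}
#'   (list-column of character vectors), \code{label}, \code{receptor},
#'   \code{effector} (logical annotation flags, may be all \code{NA}).
#' @slot edges data.frame with columns \code{source}, \code{target},
#'   \code{sign} (\code{"activation"} or \code{"inhibition"}).
#'
#' @seealso [pathwayGraph()], [loadPathway()], [extractEffectorCircuits()]
#' @export
setClass("PathwayGraph",
         representation(pathwayId = "character",
                        nodes = "data.frame",
                        edges = "data.frame"))

setValidity("PathwayGraph", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msgs <- character()
  if (length(object@pathwayId) != 1L || !nzchar(object@pathwayId))
    msgs <- c(msgs, "pathwayId must be a single non-empty string")
  need <- c("node_id", "genes", "label", "receptor", "effector")
  if (!all(need %in% colnames(nd)))
    return("node table must have columns node_id, genes, label, receptor, effector")
  if (!all(c("source", "target", "sign") %in% colnames(ed)))
    return("edge table must have columns source, target, sign")
  if (anyDuplicated(nd$node_id))
    msgs <- c(msgs, sprintf("duplicated node id(s): %s",
                            paste(unique(nd$node_id[duplicated(nd$node_id)]),
                                  collapse = ", ")))
  if (nrow(ed)) {
    unknown <- setdiff(c(ed$source, ed$target), nd$node_id)
    if (length(unknown))
      msgs <- c(msgs, sprintf("edge references unknown node(s): %s",
                              paste(unknown, collapse = ", ")))
    bad <- setdiff(unique(ed$sign), c("activation", "inhibition"))
    if (length(bad))
      msgs <- c(msgs, sprintf("invalid edge sign(s): %s",
                              paste(bad, collapse = ", ")))
    self <- ed$source == ed$target
    if (any(self))
      msgs <- c(msgs, sprintf("self-loop on node(s): %s",
                              paste(unique(ed$source[self]), collapse = ", ")))
    key <- paste(ed$source, ed$target, sep = "\r")
    if (anyDuplicated(key))
      msgs <- c(msgs, sprintf("duplicated edge(s): %s",
                              paste(unique(gsub("\r", "->",
                                                key[duplicated(key)])),
                                    collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Receptor-to-effector signaling circuit
#'
#' The subgraph of a pathway made of every node and edge lying on at least one
#' directed path from a receptor node to one given effector node.  Circuits are
#' the unit at which signal intensity is quantified and tested.
#'
#' @slot circuitId unique identifier, \code{"<pathwayId>:<effector node_id>"}.
#' @slot pathwayId parent pathway identifier.
#' @slot effector effector node id (out-degree 0 in the parent pathway).
#' @slot receptors receptor node ids feeding this circuit.
#' @slot memberNodes all node ids on some receptor-to-effector path.
#' @slot memberEdges edge table restricted to the member subgraph.
#' @slot effectorGenes genes of the effector node (may be empty for a
#'   gene-free pseudo-node effector).
#' @slot displayName human-readable name, \code{"pathway: effector gene"},
#'   with "*"/"**" suffixes disambiguating repeated effector genes.
#'
#' @export
setClass("Circuit",
         representation(circuitId = "character",
                        pathwayId = "character",
                        effector = "character",
                        receptors = "character",
                        memberNodes = "character",
                        memberEdges = "data.frame",
                        effectorGenes = "character",
                        displayName = "character"))

setValidity("Circuit", function(object) {
  msgs <- character()
  if (!(object@effector %in% object@memberNodes))
    msgs <- c(msgs, "effector must be a member node")
  if (!all(object@receptors %in% object@memberNodes))
    msgs <- c(msgs, "every receptor must be a member node")
  ed <- object@memberEdges
  if (nrow(ed) &&
      !all(c(ed$source, ed$target) %in% object@memberNodes))
    msgs <- c(msgs, "member edges must connect member nodes")
  if (length(msgs)) msgs else TRUE
})

#' Gene expression matrix with an explicit scale
#'
#' Genes-by-samples matrix tagged with the transformation stage it is on:
#' \code{"raw"} (non-negative counts or abundances), \code{"log"}
#' (log2(x + 1) of raw), or \code{"unit"} (min-max scaled to [0, 1], the
#' scale the propagation model consumes).
#'
#' @slot values numeric matrix, rownames = gene symbols, colnames = sample ids.
#' @slot scale one of \code{"raw"}, \code{"log"}, \code{"unit"}.
#'
#' @seealso [geneExpression()], [logTransform()], [truncateQuantile()],
#'   [scaleUnit()]
#' @export
setClass("GeneExpressionMatrix",
         representation(values = "matrix", scale = "character"))

setValidity("GeneExpressionMatrix", function(object) {
  v <- object@values
  msgs <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(v)))
    msgs <- c(msgs, "duplicated gene symbols")
  if (anyDuplicated(colnames(v)))
    msgs <- c(msgs, "duplicated sample ids")
  if (!(object@scale %in% c("raw", "log", "unit")) ||
      length(object@scale) != 1L)
    msgs <- c(msgs, "scale must be one of raw, log, unit")
  if (any(!is.finite(v)))
    msgs <- c(msgs, "values must be finite")
  else if (identical(object@scale, "unit")) {
    if (any(v < 0 | v > 1))
      msgs <- c(msgs, "scale 'unit' requires all values in [0, 1]")
  } else if (any(v < 0))
    msgs <- c(msgs, "values must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Node-level activity values
#'
#' Nodes-by-samples matrix of values in [0, 1], obtained by aggregating the
#' unit-scaled expression of each node's genes.  Gene-free nodes and nodes
#' whose genes were not measured carry the neutral value and are listed in the
#' \code{flags} report.
#'
#' @slot values numeric matrix in [0, 1]; rownames = node ids.
#' @slot flags data.frame (\code{node_id}, \code{reason}) of nodes that
#'   received the neutral value.
#'
#' @seealso [nodeValues()]
#' @export
setClass("NodeValueMatrix",
         representation(values = "matrix", flags = "data.frame"))

setValidity("NodeValueMatrix", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have node rownames and sample colnames")
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    return("node values must lie in [0, 1]")
  TRUE
})

#' Circuit activity matrix
#'
#' Circuits-by-samples matrix of propagated effector signal intensities, with
#' a per-circuit convergence report (\code{circuit_id}, \code{converged},
#' \code{iterations}, \code{starved}).  \code{starved} marks circuits whose
#' effector cannot be reached from any receptor through activation edges
#' alone; their activity is 0 by construction.
#'
#' @seealso [computeActivityMatrix()]
#' @export
setClass("CircuitActivityMatrix",
         representation(activity = "matrix", report = "data.frame"))

setValidity("CircuitActivityMatrix", function(object) {
  a <- object@activity
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("activity must have circuit rownames and sample colnames")
  if (any(!is.finite(a)) || any(a < 0 | a > 1))
    return("activities must lie in [0, 1]")
  if (!identical(rownames(a), object@report$circuit_id))
    return("report rows must match activity rows")
  TRUE
})

#' Result of propagating one circuit for one sample
#'
#' @slot circuit the [Circuit-class] that was evaluated.
#' @slot nodeSignal named numeric, signal intensity per member node.
#' @slot initialSignal activation input injected at receptors (default 1).
#' @slot converged logical; always TRUE on acyclic circuits (one topological
#'   sweep); on cyclic circuits, whether fixed-point iteration reached the
#'   tolerance before \code{maxIter}.
#' @slot iterations number of sweeps performed.
#' @slot starved TRUE when the effector has no activation-only path from any
#'   receptor, so the circuit activity is structurally 0.
#'
#' @seealso [propagateCircuit()]
#' @export
setClass("PropagationState",
         representation(circuit = "Circuit",
                        nodeSignal = "numeric",
                        initialSignal = "numeric",
                        converged = "logical",
                        iterations = "integer",
                        starved = "logical"))

setValidity("PropagationState", function(object) {
  s <- object@nodeSignal
  if (any(!is.finite(s)) || any(s < 0 | s > 1))
    return("node signals must lie in [0, 1]")
  TRUE
})

#' Drug specification for in-silico knockdown
#'
#' A drug is modelled by the genes it targets; simulation replaces the
#' unit-scaled expression of every target gene by \code{knockdownValue}
#' (default 0.001), a near-zero value standing for an inhibited but not
#' absolutely silenced gene product.
#'
#' @seealso [drugSpec()], [applyKnockdown()], [simulateDrug()]
#' @export
setClass("DrugSpec",
         representation(drugName = "character",
                        targets = "character",
                        knockdownValue = "numeric"))

setValidity("DrugSpec", function(object) {
  msgs <- character()
  if (length(object@drugName) != 1L || !nzchar(object@drugName))
    msgs <- c(msgs, "drugName must be a single non-empty string")
  if (length(object@targets) < 1L || any(!nzchar(object@targets)))
    msgs <- c(msgs, "targets must be a non-empty list of gene symbols")
  kv <- object@knockdownValue
  if (length(kv) != 1L || !is.finite(kv) || kv <= 0 || kv >= 1)
    msgs <- c(msgs, "knockdownValue must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Per-patient log2 fold changes of circuit activity
#'
#' Circuits-by-samples matrix of \code{log2((treated + eps) / (reference +
#' eps))}, the per-patient effect of a simulated drug on each circuit.
#'
#' @slot fc numeric matrix of log2 fold changes (finite by construction).
#' @slot epsilon additive stabilizer used in the ratio.
#'
#' @seealso [simulateDrug()], [differentialDrugEffect()]
#' @export
setClass("FoldChangeMatrix",
         representation(fc = "matrix", epsilon = "numeric"))

setValidity("FoldChangeMatrix", function(object) {
  if (any(!is.finite(object@fc)))
    return("fold changes must be finite (epsilon-stabilized)")
  if (length(object@epsilon) != 1L || object@epsilon <= 0)
    return("epsilon must be a single positive number")
  if (is.null(rownames(object@fc)) || is.null(colnames(object@fc)))
    return("fc must have circuit rownames and sample colnames")
  TRUE
})

#' Synthetic study scenario with known ground truth
#'
#' Bundles generated pathway graphs, a two-group raw expression matrix,
#' sample labels, optional drugs, and the ground-truth circuit sets against
#' which differential calls are scored.
#'
#' @slot graphs list of [PathwayGraph-class].
#' @slot expression raw-scale [GeneExpressionMatrix-class].
#' @slot labels named factor, sample id -> group.
#' @slot drugs list of [DrugSpec-class] (possibly empty).
#' @slot deCircuits circuits containing >= 1 group-biased gene on an
#'   activation-only path to the effector.
#' @slot truthGsdsa circuits expected differentially active (equals
#'   \code{deCircuits} when the planted effect is >= 1 log2 unit, else empty).
#' @slot truthNull circuits containing no group-biased gene at all.
#' @slot seed master seed; regeneration with the same seed and params is
#'   bit-identical.
#' @slot params list of all generation parameters.
#'
#' @seealso [generateScenario()], [evaluateRecovery()]
#' @export
setClass("SyntheticScenario",
         representation(graphs = "list",
                        expression = "GeneExpressionMatrix",
                        labels = "factor",
                        drugs = "list",
                        deCircuits = "character",
                        truthGsdsa = "character",
                        truthNull = "character",
                        seed = "integer",
                        params = "list"))

setValidity("SyntheticScenario", function(object) {
  msgs <- character()
  if (length(intersect(object@truthGsdsa, object@truthNull)))
    msgs <- c(msgs, "truthGsdsa and truthNull must be disjoint")
  if (!all(vapply(object@graphs, is, logical(1), "PathwayGraph")))
    msgs <- c(msgs, "graphs must all be PathwayGraph objects")
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by sample id")
  if (length(msgs)) msgs else TRUE
})
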