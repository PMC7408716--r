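#' Construct a pathway graph from node and edge tables
#'
#' @param nodes data.frame with at least \code{node_id} and \code{genes}
#'   columns; \code{genes} may be a character column (delimiter-joined) or a
#'   list-column of character vectors.  Optional columns \code{label},
#'   \code{receptor}, \code{effector} (0/1 annotation flags).
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{sign}.
#' @param pathwayId pathway identifier.
#' @param geneDelim delimiter splitting the \code{genes} column.
#' @param signAliases named character vector mapping extra sign tokens to
#'   \code{"activation"}/\code{"inhibition"}; matching is case-insensitive and
#'   the canonical tokens are always accepted.
#' @param collapseDuplicates collapse duplicated identical edges with a
#'   warning (duplicated edges with conflicting signs are always an error:
#'   the propagation rule defines no combination for them).
#'
#' @return a validated [PathwayGraph-class].
#' @examples
#' g <- pathwayGraph(
#'   nodes = data.frame(node_id = c("R", "M", "E"),
#'                      genes = c("GR", "GM", "GE")),
#'   edges = data.frame(source = c("R", "M"), target = c("M", "E"),
#'                      sign = "activation"),
#'   pathwayId = "toy")
#' findReceptors(g)
#' @export
pathwayGraph <- function(nodes, edges, pathwayId = "pathway",
                         geneDelim = ";", signAliases = character(),
                         collapseDuplicates = TRUE) {
  if (!is.data.frame(nodes) || !all(c("node_id", "genes") %in% colnames(nodes)))
    .formatError("node table must have columns node_id and genes")
  if (!is.data.frame(edges) ||
      !all(c("source", "target", "sign") %in% colnames(edges)))
    .formatError("edge table must have columns source, target, sign")

  nd <- data.frame(node_id = as.character(nodes$node_id),
                   stringsAsFactors = FALSE)
  nd$genes <- if (is.list(nodes$genes)) {
    lapply(nodes$genes, as.character)
  } else {
    .splitGenes(nodes$genes, geneDelim)
  }
  nd$label <- if ("label" %in% colnames(nodes))
    as.character(nodes$label) else nd$node_id
  nd$receptor <- if ("receptor" %in% colnames(nodes))
    !is.na(nodes$receptor) & nodes$receptor %in% c(1, "1", TRUE, "TRUE")
  else rep(NA, nrow(nd))
  nd$effector <- if ("effector" %in% colnames(nodes))
    !is.na(nodes$effector) & nodes$effector %in% c(1, "1", TRUE, "TRUE")
  else rep(NA, nrow(nd))

  ed <- data.frame(source = as.character(edges$source),
                   target = as.character(edges$target),
                   sign = .normalizeSigns(edges$sign, signAliases),
                   stringsAsFactors = FALSE)

  if (nrow(ed)) {
    self <- ed$source == ed$target
    if (any(self))
      .integrityError("self-loop edge on node(s): %s",
                      paste(unique(ed$source[self]), collapse = ", "))
    key <- paste(ed$source, ed$target, sep = "\r")
    if (anyDuplicated(key)) {
      signsPerKey <- tapply(ed$sign, key, function(s) length(unique(s)))
      conflict <- names(signsPerKey)[signsPerKey > 1]
      if (length(conflict))
        .integrityError("conflicting signs on duplicated edge(s): %s",
                        paste(gsub("\r", "->", conflict), collapse = ", "))
      if (!collapseDuplicates)
        .integrityError("duplicated edge(s): %s",
                        paste(gsub("\r", "->", unique(key[duplicated(key)])),
                              collapse = ", "))
      warning(sprintf("collapsed %d duplicated edge(s)",
                      sum(duplicated(key))))
      ed <- ed[!duplicated(key), , drop = FALSE]
      rownames(ed) <- NULL
    }
    unknown <- setdiff(c(ed$source, ed$target), nd$node_id)
    if (length(unknown))
      .integrityError("edge references unknown node(s): %s",
                      paste(unknown, collapse = ", "))
  }

  new("PathwayGraph", pathwayId = as.character(pathwayId),
      nodes = nd, edges = ed)
}

.normalizeSigns <- function(sign, aliases = character()) {
  canon <- c(activation = "activation", inhibition = "inhibition")
  if (length(aliases)) {
    bad <- setdiff(unique(aliases), c("activation", "inhibition"))
    if (length(bad))
      .formatError("sign aliases must map to activation/inhibition, got: %s",
                   paste(bad, collapse = ", "))
    names(aliases) <- tolower(names(aliases))
    canon <- c(canon, aliases)
  }
  key <- tolower(trimws(as.character(sign)))
  out <- unname(canon[key])
  if (anyNA(out))
    .formatError("unknown edge sign token(s): %s",
                 paste(unique(sign[is.na(out)]), collapse = ", "))
  out
}

#' Load one pathway from node/edge TSV files
#'
#' The node TSV must have columns \code{node_id} and \code{genes}
#' (delimiter-joined, may be empty for pseudo-nodes), optionally
#' \code{label}, \code{receptor}, \code{effector}.  The edge TSV must have
#' columns \code{source}, \code{target}, \code{sign}.
#'
#' @inheritParams pathwayGraph
#' @param nodeFile,edgeFile paths to TSV files.
#' @return a validated [PathwayGraph-class].
#' @seealso [loadPathways()] for multi-pathway files with a
#'   \code{pathway_id} column.
#' @export
loadPathway <- function(nodeFile, edgeFile, pathwayId = NULL,
                        geneDelim = ";", signAliases = character()) {
  nd <- .readTsv(nodeFile, required = c("node_id", "genes"), what = "node")
  ed <- .readTsv(edgeFile, required = c("source", "target", "sign"),
                 what = "edge")
  if (is.null(pathwayId)) {
    pathwayId <- if ("pathway_id" %in% colnames(nd) && nrow(nd))
      as.character(nd$pathway_id[1])
    else sub("\\.(tsv|txt)(\\.gz)?$", "", basename(nodeFile))
  }
  pathwayGraph(nd, ed, pathwayId = pathwayId, geneDelim = geneDelim,
               signAliases = signAliases)
}

#' Load several pathways from combined TSV files
#'
#' Node and edge tables carry a \code{pathway_id} column; rows are split by
#' pathway and each group is validated as its own graph.  Files without a
#' \code{pathway_id} column load as a single pathway.
#'
#' @inheritParams loadPathway
#' @return named list of [PathwayGraph-class] objects, ordered by pathway id.
#' @export
loadPathways <- function(nodeFile, edgeFile, geneDelim = ";",
                         signAliases = character()) {
  nd <- .readTsv(nodeFile, required = c("node_id", "genes"), what = "node")
  ed <- .readTsv(edgeFile, required = c("source", "target", "sign"),
                 what = "edge")
  if (!("pathway_id" %in% colnames(nd)))
    return(stats::setNames(
      list(pathwayGraph(nd, ed, pathwayId = "pathway",
                        geneDelim = geneDelim, signAliases = signAliases)),
      "pathway"))
  if (!("pathway_id" %in% colnames(ed)))
    .formatError("edge file must carry pathway_id when the node file does")
  ids <- sort(unique(as.character(nd$pathway_id)))
  out <- lapply(ids, function(pid) {
    pathwayGraph(nd[nd$pathway_id == pid, , drop = FALSE],
                 ed[ed$pathway_id == pid, , drop = FALSE],
                 pathwayId = pid, geneDelim = geneDelim,
                 signAliases = signAliases)
  })
  stats::setNames(out, ids)
}

.asIgraph <- function(graph, edges = graph@edges,
                      nodes = graph@nodes$node_id) {
  igraph::graph_from_data_frame(
    edges[, c("source", "target", "sign"), drop = FALSE],
    directed = TRUE, vertices = data.frame(name = nodes))
}

#' Receptor nodes of a pathway
#'
#' Receptors default to the nodes with in-degree 0.  When the node table
#' carries explicit receptor annotations (any \code{receptor} flag set) they
#' override topology; for a fully cyclic, unannotated graph no receptor is
#' derivable and a structural error is raised.
#'
#' @param graph a [PathwayGraph-class].
#' @return character vector of receptor node ids (sorted).
#' @export
findReceptors <- function(graph) {
  stopifnot(is(graph, "PathwayGraph"))
  flags <- graph@nodes$receptor
  if (!all(is.na(flags)) && any(flags, na.rm = TRUE))
    return(sort(graph@nodes$node_id[which(flags)]))
  indeg <- igraph::degree(.asIgraph(graph), mode = "in")
  rec <- sort(names(indeg)[indeg == 0])
  if (!length(rec))
    .structuralError(
      "pathway '%s': no in-degree-0 node and no receptor annotation",
      graph@pathwayId)
  rec
}

#' Effector nodes of a pathway
#'
#' Effectors default to the nodes with out-degree 0; explicit \code{effector}
#' annotations override topology, and a fully cyclic unannotated graph raises
#' a structural error.
#'
#' @param graph a [PathwayGraph-class].
#' @return character vector of effector node ids (sorted).
#' @export
findEffectors <- function(graph) {
  stopifnot(is(graph, "PathwayGraph"))
  flags <- graph@nodes$effector
  if (!all(is.na(flags)) && any(flags, na.rm = TRUE))
    return(sort(graph@nodes$node_id[which(flags)]))
  outdeg <- igraph::degree(.asIgraph(graph), mode = "out")
  eff <- sort(names(outdeg)[outdeg == 0])
  if (!length(eff))
    .structuralError(
      "pathway '%s': no out-degree-0 node and no effector annotation",
      graph@pathwayId)
  eff
}

#' Decompose a pathway into effector circuits
#'
#' One circuit is built per effector node reachable from at least one
#' receptor: its members are every node and edge lying on some directed
#' receptor-to-effector walk, computed as the intersection of the set
#' forward-reachable from the receptors with the set backward-reachable from
#' the effector.  Effectors unreachable from all receptors are skipped with a
#' warning.  Output is ordered by effector node id; display names follow the
#' "pathway: effector gene" convention with "*"/"**" suffixes when the same
#' effector gene closes more than one circuit in the pathway.
#'
#' @param graph a [PathwayGraph-class] with at least one receptor and one
#'   effector.
#' @return list of [Circuit-class] objects.
#' @export
extractEffectorCircuits <- function(graph) {
  stopifnot(is(graph, "PathwayGraph"))
  recs <- findReceptors(graph)
  effs <- findEffectors(graph)
  ig <- .asIgraph(graph)

  forward <- unique(names(unlist(lapply(recs, function(r)
    igraph::subcomponent(ig, r, mode = "out")))))

  circuits <- list()
  for (eff in effs) {
    backward <- names(igraph::subcomponent(ig, eff, mode = "in"))
    members <- intersect(forward, backward)
    # a real circuit needs at least one edge: an isolated node that is both
    # source and sink does not constitute a receptor-to-effector path
    hasEdge <- any(graph@edges$source %in% members &
                     graph@edges$target %in% members)
    if (!length(members) || !any(recs %in% members) || !hasEdge) {
      warning(sprintf("pathway '%s': effector '%s' unreachable from any receptor; circuit omitted",
                      graph@pathwayId, eff))
      next
    }
    members <- sort(members)
    ed <- graph@edges
    # an edge u->v with both endpoints members lies on a receptor->effector
    # walk (u is reachable from a receptor, v reaches the effector)
    keep <- ed$source %in% members & ed$target %in% members
    medges <- ed[keep, , drop = FALSE]
    rownames(medges) <- NULL
    circuits[[length(circuits) + 1L]] <- new(
      "Circuit",
      circuitId = paste0(graph@pathwayId, ":", eff),
      pathwayId = graph@pathwayId,
      effector = eff,
      receptors = sort(intersect(recs, members)),
      memberNodes = members,
      memberEdges = medges,
      effectorGenes = as.character(
        graph@nodes$genes[[match(eff, graph@nodes$node_id)]]),
      displayName = NA_character_)
  }
  circuits <- circuits[order(vapply(circuits, function(c) c@effector,
                                    character(1)))]
  .assignDisplayNames(circuits, graph)
}

# "pathway: gene", with "*", "**", ... appended when the same effector gene
# labels several circuits of one pathway (display only; circuitId is unique)
.assignDisplayNames <- function(circuits, graph) {
  if (!length(circuits)) return(circuits)
  effGene <- vapply(circuits, function(c) {
    g <- c@effectorGenes
    if (length(g)) g[1] else c@effector
  }, character(1))
  counts <- stats::ave(seq_along(effGene), effGene, FUN = seq_along)
  for (i in seq_along(circuits)) {
    suffix <- if (counts[i] > 1) paste0(" ", strrep("*", counts[i] - 1L)) else ""
    circuits[[i]]@displayName <-
      paste0(graph@pathwayId, ": ", effGene[i], suffix)
  }
  circuits
}

#' Export circuits as a TSV table
#'
#' Writes one row per circuit: \code{circuit_id}, \code{pathway_id},
#' \code{display_name}, \code{effector}, \code{receptors} (";"-joined),
#' \code{n_member_nodes}, \code{n_member_edges}.
#'
#' @param circuits list of [Circuit-class].
#' @param file output path; \code{NULL} returns the data.frame only.
#' @return the exported data.frame, invisibly when writing.
#' @export
circuitTable <- function(circuits, file = NULL) {
  df <- data.frame(
    circuit_id = vapply(circuits, circuitId, character(1)),
    pathway_id = vapply(circuits, pathwayId, character(1)),
    display_name = vapply(circuits, displayName, character(1)),
    effector = vapply(circuits, effector, character(1)),
    receptors = vapply(circuits, function(c)
      paste(c@receptors, collapse = ";"), character(1)),
    n_member_nodes = vapply(circuits, function(c)
      length(c@memberNodes), integer(1)),
    n_member_edges = vapply(circuits, function(c)
      nrow(c@memberEdges), integer(1)),
    stringsAsFactors = FALSE)
  if (is.null(file)) return(df)
  .writeTsv(df, file)
  invisible(df)
}
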