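#' Generate a random layered signaling pathway
#'
#' Builds a signed directed graph by layered DAG construction: receptors
#' form the first layer, effectors the last, and intermediates are spread
#' over layers of width \code{layerWidth} in between; edges run only between
#' adjacent layers (downstream), so receptors have in-degree 0 and effectors
#' out-degree 0 and circuits have the branching, mostly tree-like shape of
#' curated signaling pathways rather than a single densely chorded spine.
#' An activation backbone (every non-receptor node receives one activation
#' edge from a random node of the previous layer; every receptor feeds at
#' least one node of the next layer) guarantees each effector is reachable
#' from a receptor through activation edges.  Every remaining adjacent-layer
#' pair is connected independently with probability \code{pEdge}, signed
#' inhibitory with probability \code{pInhibition}; with \code{allowCycles},
#' sparse feedback edges from a layer to the previous one are injected.
#' Each node carries one synthetic gene by default (\code{"g_<node_id>"});
#' node ids are prefixed by the pathway id so multi-pathway scenarios have
#' globally unique nodes and genes.
#'
#' @param nNodes total nodes (>= nReceptors + nEffectors).
#' @param pEdge probability of each optional adjacent-layer edge.
#' @param pInhibition probability an optional edge is inhibitory.
#' @param nReceptors,nEffectors receptor/effector counts.
#' @param allowCycles inject feedback edges between adjacent layers.
#' @param layerWidth target intermediate nodes per layer.
#' @param nGenesPerNode genes per node.
#' @param pathwayId pathway identifier (also the node-id prefix).
#' @param seed integer seed; same seed and parameters give identical graphs.
#' @return a [PathwayGraph-class].
#' @export
generatePathway <- function(nNodes = 12L, pEdge = 0.25, pInhibition = 0.15,
                            nReceptors = 2L, nEffectors = 2L,
                            allowCycles = FALSE, layerWidth = 2L,
                            nGenesPerNode = 1L,
                            pathwayId = "P1", seed = 1L) {
  if (nNodes < nReceptors + nEffectors)
    .inputError("nNodes (%d) must be >= nReceptors + nEffectors (%d)",
                nNodes, nReceptors + nEffectors)
  if (nReceptors < 1L || nEffectors < 1L)
    .inputError("need at least one receptor and one effector")
  if (pEdge < 0 || pEdge > 1 || pInhibition < 0 || pInhibition > 1)
    .inputError("probabilities must lie in [0, 1]")
  if (layerWidth < 1L) .inputError("layerWidth must be >= 1")

  ids <- paste0(pathwayId, "_n", sprintf("%02d", seq_len(nNodes)))
  recIdx <- seq_len(nReceptors)
  effIdx <- seq(nNodes - nEffectors + 1L, nNodes)
  midIdx <- setdiff(seq_len(nNodes), c(recIdx, effIdx))
  # layer assignment: receptors | intermediates in blocks | effectors
  nMidLayers <- if (length(midIdx)) ceiling(length(midIdx) / layerWidth) else 0L
  layerOf <- integer(nNodes)
  layerOf[recIdx] <- 0L
  if (length(midIdx))
    layerOf[midIdx] <- rep(seq_len(nMidLayers), each = layerWidth,
                           length.out = length(midIdx))
  layerOf[effIdx] <- nMidLayers + 1L
  layers <- split(seq_len(nNodes), layerOf)

  .withSeed(seed, {
    src <- character(); tgtv <- character(); sgn <- character()
    addEdge <- function(i, j, sign) {
      src <<- c(src, ids[i]); tgtv <<- c(tgtv, ids[j])
      sgn <<- c(sgn, sign)
    }
    nLayers <- length(layers)
    # backbone: one activation parent in the previous layer per node
    for (li in seq_len(nLayers - 1L)) {
      prev <- layers[[li]]; cur <- layers[[li + 1L]]
      for (j in cur) addEdge(if (length(prev) > 1L) sample(prev, 1L)
                             else prev, j, "activation")
    }
    have <- paste(src, tgtv)
    # receptors that ended up childless feed a random next-layer node
    if (nLayers > 1L) {
      for (r in layers[[1L]]) {
        if (!any(src == ids[r])) {
          nxt <- layers[[2L]]
          j <- if (length(nxt) > 1L) sample(nxt, 1L) else nxt
          addEdge(r, j, "activation")
          have <- c(have, paste(ids[r], ids[j]))
        }
      }
    }
    # optional adjacent-layer edges
    for (li in seq_len(nLayers - 1L)) {
      for (i in layers[[li]]) for (j in layers[[li + 1L]]) {
        if (paste(ids[i], ids[j]) %in% have) next
        if (stats::runif(1) < pEdge) {
          sign <- if (stats::runif(1) < pInhibition) "inhibition"
                  else "activation"
          addEdge(i, j, sign)
          have <- c(have, paste(ids[i], ids[j]))
        }
      }
    }
    # sparse feedback edges (intermediate layers only)
    if (allowCycles && nLayers > 2L) {
      for (li in 2L:(nLayers - 1L)) {
        for (i in layers[[li]]) for (j in layers[[li - 1L]]) {
          if (j %in% recIdx) next
          if (paste(ids[i], ids[j]) %in% have) next
          if (stats::runif(1) < pEdge / 2) {
            sign <- if (stats::runif(1) < pInhibition) "inhibition"
                    else "activation"
            addEdge(i, j, sign)
            have <- c(have, paste(ids[i], ids[j]))
          }
        }
      }
    }
    genes <- lapply(ids, function(id)
      if (nGenesPerNode == 1L) paste0("g_", id)
      else paste0("g_", id, "_", seq_len(nGenesPerNode)))
    nodes <- data.frame(node_id = ids, stringsAsFactors = FALSE)
    nodes$genes <- genes
    nodes$label <- ids
    nodes$receptor <- seq_len(nNodes) %in% recIdx
    nodes$effector <- seq_len(nNodes) %in% effIdx
    edges <- data.frame(source = src, target = tgtv, sign = sgn,
                        stringsAsFactors = FALSE)
    pathwayGraph(nodes, edges, pathwayId = pathwayId)
  })
}

#' Generate two-group negative-binomial expression counts
#'
#' Gene-level baseline means are log-normal across genes around
#' \code{baseMean}; counts are drawn per gene and sample from a negative
#' binomial with that mean and the stated dispersion (variance
#' \eqn{\mu + \phi \mu^2}), mirroring the RNA-seq provenance of the real
#' inputs with equal library sizes by construction.  Genes in
#' \code{deGenes} have their mean multiplied by \code{2^effectLog2fc} in
#' group 1 only.
#'
#' @param graphs [PathwayGraph-class] or list of them; genes are the union
#'   of node genes.
#' @param nPerGroup samples per group (>= 3).
#' @param deGenes character vector of group-biased genes (subset of the
#'   graph genes; may be empty).
#' @param effectLog2fc planted log2 fold change in group 1.
#' @param dispersion NB dispersion \eqn{\phi} (Poisson limit as it tends
#'   to 0).
#' @param baseMean median baseline mean count.
#' @param sdLog log-scale spread of baseline means across genes.
#' @param groups length-2 character vector of group names.
#' @param seed integer seed.
#' @return list with \code{expression} (raw [GeneExpressionMatrix-class])
#'   and \code{labels} (named factor).
#' @export
generateExpression <- function(graphs, nPerGroup = 30L,
                               deGenes = character(),
                               effectLog2fc = 1, dispersion = 0.1,
                               baseMean = 200, sdLog = 1,
                               groups = c("G1", "G2"), seed = 1L) {
  if (is(graphs, "PathwayGraph")) graphs <- list(graphs)
  if (nPerGroup < 3L) .inputError("nPerGroup must be >= 3")
  genes <- unique(unlist(lapply(graphs, function(g) g@nodes$genes)))
  if (!length(genes)) .inputError("graphs carry no genes")
  bad <- setdiff(deGenes, genes)
  if (length(bad))
    .inputError("deGenes not present in the graphs: %s",
                paste(bad, collapse = ", "))

  nS <- 2L * nPerGroup
  sampleIds <- sprintf("S%03d", seq_len(nS))
  labels <- factor(rep(groups, each = nPerGroup), levels = groups)
  names(labels) <- sampleIds

  .withSeed(seed, {
    mu <- stats::rlnorm(length(genes), meanlog = log(baseMean),
                        sdlog = sdLog)
    names(mu) <- genes
    size <- if (dispersion > 0) 1 / dispersion else Inf
    counts <- matrix(0, length(genes), nS,
                     dimnames = list(genes, sampleIds))
    for (g in genes) {
      m <- rep(mu[g], nS)
      if (g %in% deGenes) m[labels == groups[1]] <- m[labels == groups[1]] *
          2^effectLog2fc
      counts[g, ] <- if (is.finite(size))
        stats::rnbinom(nS, mu = m, size = size)
      else stats::rpois(nS, lambda = m)
    }
    list(expression = geneExpression(counts, scale = "raw"),
         labels = labels)
  })
}

#' Generate a complete synthetic study scenario
#'
#' Draws \code{nPathways} random pathways, picks the group-biased gene set
#' (either an explicit vector or \code{deGenes = <count>} genes sampled from
#' the union of node genes), simulates two-group expression, and derives the
#' ground truth against which differential calls are scored: a circuit
#' belongs to \code{deCircuits} when at least one of its member nodes holds
#' a group-biased gene with an activation-only path to the effector; circuits
#' containing no group-biased gene form the null set; the expected
#' differential set equals \code{deCircuits} when \code{effectLog2fc >= 1}
#' (weaker planted effects leave it empty, and circuits in neither set are
#' excluded from recovery metrics).  Optionally one drug per scenario is
#' specified, targeting the sole gene of the first pathway's first receptor.
#'
#' @param nPathways number of pathways.
#' @param nNodes nodes per pathway.
#' @param deGenes integer count (sampled) or explicit character vector.
#' @param withDrug include a receptor-targeting [DrugSpec-class].
#' @param seed master seed; sub-seeds for graphs and expression are derived
#'   from it.
#' @inheritParams generatePathway
#' @inheritParams generateExpression
#' @param ... further arguments to [generatePathway()].
#' @return a [SyntheticScenario-class].
#' @export
generateScenario <- function(nPathways = 5L, nNodes = 12L, nPerGroup = 30L,
                             deGenes = 10L, effectLog2fc = 1,
                             dispersion = 0.1, baseMean = 200, sdLog = 1,
                             pEdge = 0.25, pInhibition = 0.15,
                             nReceptors = 2L, nEffectors = 2L,
                             allowCycles = FALSE,
                             groups = c("G1", "G2"), withDrug = FALSE,
                             seed = 1L) {
  # keep derived sub-seeds well inside 32-bit integer range
  seed <- abs(as.integer(seed)) %% 1000003L
  graphs <- lapply(seq_len(nPathways), function(k)
    generatePathway(nNodes = nNodes, pEdge = pEdge,
                    pInhibition = pInhibition, nReceptors = nReceptors,
                    nEffectors = nEffectors, allowCycles = allowCycles,
                    pathwayId = sprintf("P%02d", k),
                    seed = seed * 131L + k))
  names(graphs) <- vapply(graphs, pathwayId, character(1))
  allGenes <- unique(unlist(lapply(graphs, function(g) g@nodes$genes)))
  if (is.numeric(deGenes)) {
    nDe <- as.integer(deGenes)
    if (nDe > length(allGenes))
      .inputError("cannot sample %d de genes from %d available",
                  nDe, length(allGenes))
    deGenes <- .withSeed(seed + 7L, sort(sample(allGenes, nDe)))
  }
  ex <- generateExpression(graphs, nPerGroup = nPerGroup,
                           deGenes = deGenes,
                           effectLog2fc = effectLog2fc,
                           dispersion = dispersion, baseMean = baseMean,
                           sdLog = sdLog, groups = groups,
                           seed = seed + 1000L)
  circuits <- unlist(lapply(graphs, extractEffectorCircuits),
                     recursive = FALSE)
  truth <- .classifyCircuits(circuits, graphs, deGenes)
  drugs <- list()
  if (withDrug) {
    # target a receptor that actually feeds a circuit, so the simulated
    # drug exercises the knockdown machinery
    rec1 <- circuits[[1]]@receptors[1]
    g1 <- graphs[[which(vapply(graphs, function(g)
      rec1 %in% g@nodes$node_id, logical(1)))[1]]]
    target <- g1@nodes$genes[[match(rec1, g1@nodes$node_id)]][1]
    drugs <- list(drugSpec("syntheticDrug", target))
  }
  new("SyntheticScenario",
      graphs = graphs,
      expression = ex$expression,
      labels = ex$labels,
      drugs = drugs,
      deCircuits = truth$de,
      truthGsdsa = if (effectLog2fc >= 1) truth$de else character(),
      truthNull = truth$null,
      seed = seed,
      params = list(nPathways = nPathways, nNodes = nNodes,
                    nPerGroup = nPerGroup, deGenes = deGenes,
                    effectLog2fc = effectLog2fc, dispersion = dispersion,
                    baseMean = baseMean, sdLog = sdLog, pEdge = pEdge,
                    pInhibition = pInhibition, nReceptors = nReceptors,
                    nEffectors = nEffectors, allowCycles = allowCycles,
                    groups = groups, withDrug = withDrug))
}

# de circuits: >=1 member node holding a de gene with an activation-only
# path to the effector; null circuits: no de gene among member nodes
.classifyCircuits <- function(circuits, graphs, deGenes) {
  nodeGenes <- do.call(rbind, lapply(graphs, function(g)
    data.frame(node_id = g@nodes$node_id,
               hasDe = vapply(g@nodes$genes, function(gs)
                 any(gs %in% deGenes), logical(1)),
               stringsAsFactors = FALSE)))
  deNodes <- nodeGenes$node_id[nodeGenes$hasDe]
  de <- character(); null <- character()
  for (c in circuits) {
    inDe <- intersect(c@memberNodes, deNodes)
    if (!length(inDe)) { null <- c(null, c@circuitId); next }
    actEd <- c@memberEdges[c@memberEdges$sign == "activation", ,
                           drop = FALSE]
    ag <- .asIgraph(NULL, edges = actEd, nodes = c@memberNodes)
    back <- names(igraph::subcomponent(ag, c@effector, mode = "in"))
    if (any(inDe %in% back)) de <- c(de, c@circuitId)
    # circuits whose de genes reach the effector only through inhibition
    # stay unlabeled: the direction of their shift is sign-ambiguous
  }
  list(de = sort(de), null = sort(null))
}

#' Score differential calls against a scenario's ground truth
#'
#' @param results result table from [differentialSignaling()].
#' @param scenario a [SyntheticScenario-class].
#' @param alpha FDR threshold defining a positive call.
#' @return named numeric: \code{sensitivity} (over the true differential
#'   set; \code{NA} when that set is empty), \code{specificity} (over the
#'   null set), \code{observed_fdr} (false positives among labeled positive
#'   calls, 0/0 counted as 0).
#' @export
evaluateRecovery <- function(results, scenario, alpha = 0.05) {
  stopifnot(is(scenario, "SyntheticScenario"))
  truth <- scenario@truthGsdsa
  nullSet <- scenario@truthNull
  known <- union(truth, nullSet)
  missing <- setdiff(known, results$circuit_id)
  if (length(missing))
    .inputError("results lack truth circuit(s): %s",
                paste(missing, collapse = ", "))
  called <- results$circuit_id[results$fdr_p < alpha]
  tp <- length(intersect(called, truth))
  fp <- length(intersect(called, nullSet))
  sens <- if (length(truth)) tp / length(truth) else NA_real_
  spec <- if (length(nullSet)) 1 - fp / length(nullSet) else NA_real_
  labeledCalls <- length(intersect(called, known))
  fdr <- if (labeledCalls) fp / labeledCalls else 0
  c(sensitivity = sens, specificity = spec, observed_fdr = fdr)
}

#' Write a scenario to a directory of TSV files
#'
#' Emits \code{nodes.tsv}, \code{edges.tsv} (with \code{pathway_id}
#' columns), \code{expr.tsv}, \code{labels.tsv}, \code{drugs.tsv} (when
#' drugs exist), \code{truth_gsdsa.tsv} and \code{truth_null.tsv}.
#'
#' @param scenario a [SyntheticScenario-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeScenario <- function(scenario, dir) {
  stopifnot(is(scenario, "SyntheticScenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- do.call(rbind, lapply(scenario@graphs, function(g)
    data.frame(pathway_id = g@pathwayId,
               node_id = g@nodes$node_id,
               genes = .joinGenes(g@nodes$genes),
               label = g@nodes$label,
               receptor = as.integer(g@nodes$receptor),
               effector = as.integer(g@nodes$effector),
               stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(scenario@graphs, function(g)
    if (nrow(g@edges)) cbind(data.frame(pathway_id = g@pathwayId,
                                        stringsAsFactors = FALSE),
                             g@edges) else NULL))
  .writeTsv(nodes, file.path(dir, "nodes.tsv"))
  .writeTsv(edges, file.path(dir, "edges.tsv"))
  .writeMatrixTsv(scenario@expression@values, file.path(dir, "expr.tsv"),
                  "gene")
  .writeTsv(data.frame(sample_id = names(scenario@labels),
                       group = as.character(scenario@labels),
                       stringsAsFactors = FALSE),
            file.path(dir, "labels.tsv"))
  if (length(scenario@drugs))
    .writeTsv(data.frame(
      drug_name = vapply(scenario@drugs, drugName, character(1)),
      targets = vapply(scenario@drugs, function(d)
        paste(d@targets, collapse = ";"), character(1)),
      stringsAsFactors = FALSE),
      file.path(dir, "drugs.tsv"))
  .writeTsv(data.frame(circuit_id = scenario@truthGsdsa),
            file.path(dir, "truth_gsdsa.tsv"))
  .writeTsv(data.frame(circuit_id = scenario@truthNull),
            file.path(dir, "truth_null.tsv"))
  invisible(dir)
}
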