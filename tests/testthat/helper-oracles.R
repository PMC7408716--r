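# Fixture builders and independent oracles used across the test files.

# --- graph fixtures --------------------------------------------------------

chainGraph <- function(n = 3, signs = rep("activation", n - 1),
                       pathwayId = "chain") {
  mids <- if (n == 3L) "M" else paste0("M", seq_len(max(0, n - 2)))
  ids <- c("R", mids, "E")[seq_len(n)]
  pathwayGraph(
    nodes = data.frame(node_id = ids, genes = paste0("g", ids),
                       stringsAsFactors = FALSE),
    edges = data.frame(source = ids[-n], target = ids[-1], sign = signs,
                       stringsAsFactors = FALSE),
    pathwayId = pathwayId)
}

diamondGraph <- function(pathwayId = "diamond") {
  pathwayGraph(
    nodes = data.frame(node_id = c("R", "A", "B", "E"),
                       genes = c("gR", "gA", "gB", "gE")),
    edges = data.frame(source = c("R", "R", "A", "B"),
                       target = c("A", "B", "E", "E"),
                       sign = "activation"),
    pathwayId = pathwayId)
}

# nodes-by-samples NodeValueMatrix from a named vector or matrix
makeNvm <- function(values) {
  if (!is.matrix(values))
    values <- matrix(values, ncol = 1,
                     dimnames = list(names(values), "s1"))
  new("NodeValueMatrix", values = values,
      flags = data.frame(node_id = character(), reason = character()))
}

# circuits-by-samples CircuitActivityMatrix from a plain matrix
makeCam <- function(m) {
  new("CircuitActivityMatrix", activity = m,
      report = data.frame(circuit_id = rownames(m), converged = TRUE,
                          iterations = 1L, starved = FALSE,
                          stringsAsFactors = FALSE))
}

# --- path enumeration (exhaustive, for small graphs) -----------------------

# all simple directed paths from -> to, as lists of node ids
enumeratePaths <- function(edges, from, to) {
  paths <- list()
  walk <- function(node, visited) {
    if (node == to) {
      paths[[length(paths) + 1L]] <<- visited
      return(invisible())
    }
    nxt <- edges$target[edges$source == node]
    for (v in setdiff(nxt, visited)) walk(v, c(visited, v))
  }
  walk(from, from)
  paths
}

# union of nodes / edges on any receptor -> effector path
pathMembership <- function(graph, receptors, effector) {
  ed <- edgeTable(graph)
  nodes <- character(); ekeys <- character()
  for (r in receptors) {
    for (p in enumeratePaths(ed, r, effector)) {
      nodes <- union(nodes, p)
      if (length(p) > 1L)
        ekeys <- union(ekeys, paste(p[-length(p)], p[-1], sep = "->"))
    }
  }
  list(nodes = sort(nodes), edges = sort(ekeys))
}

# --- propagation oracle ----------------------------------------------------

# synchronous fixed-point iteration written from the update rule definition,
# independent of the package's topological-sweep code path
fixedPointOracle <- function(circuit, v, init = 1, tol = 1e-10,
                             maxIter = 10000L) {
  members <- memberNodes(circuit)
  ed <- memberEdges(circuit)
  recs <- receptors(circuit)
  S <- v[members]
  for (it in seq_len(maxIter)) {
    Snew <- vapply(members, function(n) {
      ap <- ed$source[ed$target == n & ed$sign == "activation"]
      ip <- ed$source[ed$target == n & ed$sign == "inhibition"]
      act <- if (n %in% recs) {
        1 - (1 - init) * (if (length(ap)) prod(1 - S[ap]) else 1)
      } else if (length(ap)) 1 - prod(1 - S[ap]) else 0
      inh <- if (length(ip)) prod(1 - S[ip]) else 1
      unname(v[n] * act * inh)
    }, numeric(1))
    if (max(abs(Snew - S)) < tol) return(Snew)
    S <- Snew
  }
  S
}

# --- exact-test oracles ----------------------------------------------------

# two-sample Mann-Whitney p by exhaustive enumeration of group assignments
rankSumOracle <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  uFor <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uFor(seq_len(n1))
  us <- apply(utils::combn(length(pooled), n1), 2L, uFor)
  lo <- mean(us <= uObs); hi <- mean(us >= uObs)
  switch(alternative,
         less = lo, greater = hi,
         two.sided = min(1, 2 * min(lo, hi)))
}

# paired signed-rank p by exhaustive enumeration of sign patterns
signedRankOracle <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(1)
  r <- rank(abs(d))
  vObs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1L, function(s) sum(r[s]))
  lo <- mean(vs <= vObs); hi <- mean(vs >= vObs)
  switch(alternative,
         less = lo, greater = hi,
         two.sided = min(1, 2 * min(lo, hi)))
}

# --- multiple testing oracle -----------------------------------------------

# literal step-up definition: q_(k) = min_{j >= k} p_(j) * m / j, capped at 1
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- 1
  for (k in m:1) {
    running <- min(running, sorted[k] * m / k)
    adj[k] <- running
  }
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# --- misc ------------------------------------------------------------------

# unit-scale expression matrix with every value fixed
constantUnitExpr <- function(genes, samples, value = 1) {
  geneExpression(matrix(value, length(genes), length(samples),
                        dimnames = list(genes, samples)), scale = "unit")
}

scenarioPipeline <- function(sc, alpha = 0.05) {
  ex <- scaleUnit(truncateQuantile(logTransform(sc@expression)))
  nv <- nodeValues(ex, sc@graphs)
  circuits <- unlist(lapply(sc@graphs, extractEffectorCircuits),
                     recursive = FALSE)
  act <- suppressWarnings(computeActivityMatrix(circuits, nv))
  res <- differentialSignaling(act, sc@labels, alpha = alpha)
  list(expr = ex, nv = nv, circuits = circuits, act = act, res = res)
}
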