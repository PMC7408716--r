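#' Construct a gene expression matrix
#'
#' @param values numeric genes-by-samples matrix with gene rownames and
#'   sample colnames.
#' @param scale one of \code{"raw"}, \code{"log"}, \code{"unit"}.
#' @return a [GeneExpressionMatrix-class].
#' @export
geneExpression <- function(values, scale = c("raw", "log", "unit")) {
  scale <- match.arg(scale)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GeneExpressionMatrix", values = values, scale = scale)
}

#' Read an expression TSV (first column gene symbol, remaining columns
#' samples); gzip-compressed files are accepted.
#'
#' @param file path to the TSV.
#' @param scale scale tag to attach (default \code{"raw"}).
#' @return a [GeneExpressionMatrix-class].
#' @export
readExpression <- function(file, scale = "raw") {
  m <- .readMatrixTsv(file, what = "expression")
  geneExpression(m, scale = scale)
}

#' Write an expression or node-value matrix as TSV
#' @param x a [GeneExpressionMatrix-class], [NodeValueMatrix-class] or
#'   [CircuitActivityMatrix-class].
#' @param file output path.
#' @param idCol name for the identifier column.
#' @return the path, invisibly.
#' @export
writeMatrix <- function(x, file, idCol = "id") {
  .writeMatrixTsv(as.matrix(x), file, idCol)
  invisible(file)
}

#' log2(x + 1) transform
#'
#' @param m a raw-scale [GeneExpressionMatrix-class] (non-negative values).
#' @return the matrix on \code{"log"} scale; shape preserved.
#' @export
logTransform <- function(m) {
  stopifnot(is(m, "GeneExpressionMatrix"))
  if (m@scale != "raw")
    .domainError("logTransform expects scale 'raw', got '%s'", m@scale)
  if (any(m@values < 0))
    .domainError("logTransform requires non-negative values")
  geneExpression(log2(m@values + 1), scale = "log")
}

#' Upper-quantile truncation
#'
#' Values above the q-quantile are set to that quantile; everything else is
#' untouched.  By default the quantile is taken globally over the whole
#' matrix; \code{perGene = TRUE} truncates each gene row at its own quantile.
#'
#' @param m a [GeneExpressionMatrix-class].
#' @param q quantile in (0, 1); default 0.99.
#' @param perGene logical; per-gene instead of global truncation.
#' @return truncated matrix on the same scale.
#' @export
truncateQuantile <- function(m, q = 0.99, perGene = FALSE) {
  stopifnot(is(m, "GeneExpressionMatrix"))
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    .inputError("q must be a single fraction in (0, 1)")
  v <- m@values
  if (perGene) {
    caps <- apply(v, 1L, stats::quantile, probs = q, names = FALSE)
    v <- pmin(v, caps)  # caps recycles down columns (row-wise cap)
  } else {
    cap <- stats::quantile(as.vector(v), probs = q, names = FALSE)
    v[v > cap] <- cap
  }
  geneExpression(v, scale = m@scale)
}

#' Min-max scaling to the unit interval
#'
#' Each gene is scaled across samples to [0, 1] by
#' \eqn{(v - min) / (max - min)}.  Genes constant across samples carry no
#' ranking information and are mapped to \code{constantValue} (default 0.5,
#' the uninformative midpoint: mapping them to 0 would annihilate all
#' downstream signal through the multiplicative propagation rule for purely
#' technical reasons).
#'
#' @param m a [GeneExpressionMatrix-class] on any scale.
#' @param constantValue value assigned to constant genes.
#' @return the matrix on \code{"unit"} scale.
#' @export
scaleUnit <- function(m, constantValue = 0.5) {
  stopifnot(is(m, "GeneExpressionMatrix"))
  if (!is.numeric(constantValue) || constantValue < 0 || constantValue > 1)
    .inputError("constantValue must lie in [0, 1]")
  v <- m@values
  lo <- apply(v, 1L, min)
  hi <- apply(v, 1L, max)
  span <- hi - lo
  const <- span == 0
  span[const] <- 1  # avoid 0/0; rows overwritten below
  out <- (v - lo) / span
  out[const, ] <- constantValue
  # guard float excursions like (x - lo)/span = 1 + 2e-16
  out <- pmin(pmax(out, 0), 1)
  geneExpression(out, scale = "unit")
}

#' Aggregate unit-scaled gene expression into node activity values
#'
#' Each pathway node's value per sample is the mean (default), min, or max of
#' its genes' unit-scaled expression.  Gene-free nodes (e.g. metabolites) and
#' nodes none of whose genes were measured transmit neutrally: they get the
#' value \code{neutralValue} (default 1) so that missing evidence does not
#' destroy circuit signal; every such node is listed in the returned flag
#' report for audit.
#'
#' @param m a unit-scale [GeneExpressionMatrix-class].
#' @param graphs a [PathwayGraph-class] or list of them; node ids must be
#'   unique across the supplied graphs.
#' @param rule aggregation rule over a node's measured genes.
#' @param neutralValue value for gene-free/unmeasured nodes, in [0, 1].
#' @return a [NodeValueMatrix-class]; see [flaggedNodes()] for the report.
#' @export
nodeValues <- function(m, graphs, rule = c("mean", "min", "max"),
                       neutralValue = 1) {
  stopifnot(is(m, "GeneExpressionMatrix"))
  rule <- match.arg(rule)
  if (m@scale != "unit")
    .domainError("nodeValues expects scale 'unit', got '%s'", m@scale)
  if (!is.numeric(neutralValue) || neutralValue < 0 || neutralValue > 1)
    .inputError("neutralValue must lie in [0, 1]")
  if (is(graphs, "PathwayGraph")) graphs <- list(graphs)
  nodeIds <- unlist(lapply(graphs, function(g) g@nodes$node_id))
  if (anyDuplicated(nodeIds))
    .integrityError("node ids must be unique across pathways; duplicated: %s",
                    paste(unique(nodeIds[duplicated(nodeIds)]),
                          collapse = ", "))
  geneLists <- unlist(lapply(graphs, function(g) g@nodes$genes),
                      recursive = FALSE)

  v <- m@values
  aggFun <- switch(rule, mean = colMeans,
                   min = function(x) apply(x, 2L, min),
                   max = function(x) apply(x, 2L, max))
  out <- matrix(neutralValue, length(nodeIds), ncol(v),
                dimnames = list(nodeIds, colnames(v)))
  flagId <- character(); flagWhy <- character()
  for (i in seq_along(nodeIds)) {
    genes <- geneLists[[i]]
    if (!length(genes)) {
      flagId <- c(flagId, nodeIds[i]); flagWhy <- c(flagWhy, "gene-free")
      next
    }
    present <- intersect(genes, rownames(v))
    if (!length(present)) {
      flagId <- c(flagId, nodeIds[i]); flagWhy <- c(flagWhy, "no measured gene")
      next
    }
    out[i, ] <- aggFun(v[present, , drop = FALSE])
  }
  new("NodeValueMatrix", values = out,
      flags = data.frame(node_id = flagId, reason = flagWhy,
                         stringsAsFactors = FALSE))
}
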