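#' Single-node signal update rule
#'
#' The signal intensity of a node with normalized expression \code{v} given
#' the activation inputs \code{A} and inhibition inputs \code{I} is
#' \deqn{S = v \cdot \left(1 - \prod_{a \in A}(1 - a)\right) \cdot
#'   \prod_{i \in I}(1 - i)}
#' An empty \code{A} yields an activation factor of 1 by the standalone-op
#' convention (a receptor's injected initial signal of 1 makes the factor 1
#' as well); an empty \code{I} yields an inhibition factor of 1.  During
#' circuit propagation, non-receptor nodes with no incoming activation edge
#' instead get the literal empty-product factor 0 — signal cannot be created
#' by inhibition alone — and the circuit is flagged; see
#' [propagateCircuit()].
#'
#' @param v node expression value in [0, 1].
#' @param A numeric vector of activation input signals in [0, 1] (may be
#'   empty).
#' @param I numeric vector of inhibition input signals in [0, 1] (may be
#'   empty).
#' @return the updated signal intensity, in [0, 1].
#' @examples
#' nodeUpdate(0.8, A = c(0.5, 0.5), I = 0.2)  # 0.48
#' @export
nodeUpdate <- function(v, A = numeric(), I = numeric()) {
  vals <- c(v, A, I)
  if (length(v) != 1L || !is.numeric(vals) || any(!is.finite(vals)) ||
      any(vals < 0 | vals > 1))
    .domainError("nodeUpdate inputs must be single values in [0, 1]")
  act <- if (length(A)) 1 - prod(1 - A) else 1
  inh <- if (length(I)) prod(1 - I) else 1
  v * act * inh
}

# Core engine: propagate one circuit for all samples at once.
# V: member-nodes x samples matrix of node values in [0,1].
# Acyclic circuits are evaluated exactly in topological order (one sweep);
# cyclic ones by synchronous (Jacobi) fixed-point iteration from S = V.
.propagateMatrix <- function(circuit, V, tol = 1e-6, maxIter = 100L,
                             initialSignal = 1) {
  members <- circuit@memberNodes
  V <- V[members, , drop = FALSE]
  ed <- circuit@memberEdges
  recs <- circuit@receptors
  isRec <- members %in% recs

  tgt <- factor(ed$target, levels = members)
  actPar <- split(ed$source[ed$sign == "activation"],
                  tgt[ed$sign == "activation"])
  inhPar <- split(ed$source[ed$sign == "inhibition"],
                  tgt[ed$sign == "inhibition"])

  ig <- .asIgraph(NULL, edges = ed, nodes = members)
  starved <- !.activationReachable(circuit, ig)

  colProd <- function(M) {
    if (nrow(M) == 1L) M[1L, ] else apply(M, 2L, prod)
  }
  updateNode <- function(n, S) {
    ap <- actPar[[n]]
    act <- if (isRec[match(n, members)]) {
      base <- 1 - initialSignal
      if (length(ap)) 1 - base * colProd(1 - S[ap, , drop = FALSE])
      else rep(1 - base, ncol(S))
    } else if (length(ap) == 1L) {
      S[ap, ]  # 1 - (1 - s) analytically; avoids cancellation at small s
    } else if (length(ap)) {
      1 - colProd(1 - S[ap, , drop = FALSE])
    } else {
      rep(0, ncol(S))  # activation-starved: empty product is 0
    }
    inh <- if (length(inhPar[[n]]))
      colProd(1 - S[inhPar[[n]], , drop = FALSE])
    else rep(1, ncol(S))
    V[n, ] * act * inh
  }

  if (igraph::is_dag(ig)) {
    S <- matrix(0, length(members), ncol(V),
                dimnames = dimnames(V))
    order <- names(igraph::topo_sort(ig, mode = "out"))
    for (n in order) S[n, ] <- updateNode(n, S)
    converged <- TRUE
    iterations <- 1L
  } else {
    S <- V
    converged <- FALSE
    iterations <- 0L
    while (iterations < maxIter) {
      Snew <- S
      for (n in members) Snew[n, ] <- updateNode(n, S)
      iterations <- iterations + 1L
      delta <- max(abs(Snew - S))
      S <- Snew
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  S <- pmin(pmax(S, 0), 1)
  list(signal = S, converged = converged, iterations = iterations,
       starved = starved)
}

# is the effector reachable from some receptor through activation edges only?
.activationReachable <- function(circuit, ig = NULL) {
  ed <- circuit@memberEdges
  actEd <- ed[ed$sign == "activation", , drop = FALSE]
  ag <- .asIgraph(NULL, edges = actEd, nodes = circuit@memberNodes)
  reach <- unique(names(unlist(lapply(circuit@receptors, function(r)
    igraph::subcomponent(ag, r, mode = "out")))))
  circuit@effector %in% reach
}

#' Propagate signal through one circuit for a single sample
#'
#' An initial signal of \code{initialSignal} (default 1) enters every
#' receptor as its activation input; the signal then flows through the member
#' nodes by the recursive product rule of [nodeUpdate()], attenuated by each
#' node's normalized expression value.  Acyclic circuits are evaluated
#' exactly in one topological sweep; cyclic circuits by synchronous
#' fixed-point iteration initialized at the node values, stopping when the
#' largest absolute change drops below \code{tol} or after \code{maxIter}
#' sweeps (non-convergence is returned, with a warning, not an error).
#' The circuit activity is the effector node's signal.
#'
#' @param circuit a [Circuit-class].
#' @param values named numeric vector of node values in [0, 1] covering all
#'   member nodes (a column of a [NodeValueMatrix-class]).
#' @param tol convergence tolerance for cyclic circuits.
#' @param maxIter sweep cap for cyclic circuits.
#' @param initialSignal activation input injected at receptors.
#' @return a [PropagationState-class].
#' @export
propagateCircuit <- function(circuit, values, tol = 1e-6, maxIter = 100L,
                             initialSignal = 1) {
  stopifnot(is(circuit, "Circuit"))
  if (!is.numeric(tol) || tol <= 0) .inputError("tol must be > 0")
  missing <- setdiff(circuit@memberNodes, names(values))
  if (length(missing))
    .inputError("missing node value(s) for circuit '%s': %s",
                circuit@circuitId, paste(missing, collapse = ", "))
  V <- matrix(values[circuit@memberNodes], ncol = 1,
              dimnames = list(circuit@memberNodes, "sample"))
  if (any(!is.finite(V)) || any(V < 0 | V > 1))
    .domainError("node values must lie in [0, 1]")
  res <- .propagateMatrix(circuit, V, tol = tol, maxIter = maxIter,
                          initialSignal = initialSignal)
  if (!res$converged)
    warning(sprintf("circuit '%s': fixed-point iteration did not converge in %d sweeps",
                    circuit@circuitId, maxIter))
  if (res$starved)
    warning(sprintf("circuit '%s': effector unreachable by activation; activity is 0",
                    circuit@circuitId))
  new("PropagationState", circuit = circuit,
      nodeSignal = stats::setNames(res$signal[, 1L],
                                   rownames(res$signal)),
      initialSignal = initialSignal,
      converged = res$converged,
      iterations = res$iterations,
      starved = res$starved)
}

#' Compute the circuit activity matrix
#'
#' Propagates every circuit over every sample of a node-value matrix; entry
#' \code{[c, s]} is the effector signal of circuit \code{c} under sample
#' \code{s}'s node values.  Row order follows the supplied circuit list,
#' column order the sample order of \code{values}.  The attached convergence
#' report records, per circuit, whether fixed-point iteration converged and
#' whether the effector is activation-starved.
#'
#' @param circuits list of [Circuit-class].
#' @param values a [NodeValueMatrix-class] covering all member nodes.
#' @inheritParams propagateCircuit
#' @return a [CircuitActivityMatrix-class].
#' @export
computeActivityMatrix <- function(circuits, values, tol = 1e-6,
                                  maxIter = 100L, initialSignal = 1) {
  stopifnot(is(values, "NodeValueMatrix"), length(circuits) >= 1L)
  V <- values@values
  ids <- unname(vapply(circuits, circuitId, character(1)))
  if (anyDuplicated(ids))
    .inputError("duplicated circuit ids: %s",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  act <- matrix(NA_real_, length(circuits), ncol(V),
                dimnames = list(ids, colnames(V)))
  converged <- logical(length(circuits))
  iterations <- integer(length(circuits))
  starved <- logical(length(circuits))
  for (k in seq_along(circuits)) {
    ck <- circuits[[k]]
    missing <- setdiff(ck@memberNodes, rownames(V))
    if (length(missing))
      .inputError("missing node value(s) for circuit '%s': %s",
                  ck@circuitId, paste(missing, collapse = ", "))
    res <- .propagateMatrix(ck, V, tol = tol, maxIter = maxIter,
                            initialSignal = initialSignal)
    act[k, ] <- res$signal[ck@effector, ]
    converged[k] <- res$converged
    iterations[k] <- res$iterations
    starved[k] <- res$starved
  }
  if (any(!converged))
    warning(sprintf("%d circuit(s) did not converge within %d sweeps",
                    sum(!converged), maxIter))
  if (any(starved))
    warning(sprintf("%d circuit(s) have activation-starved effectors (activity 0)",
                    sum(starved)))
  new("CircuitActivityMatrix", activity = act,
      report = data.frame(circuit_id = ids, converged = converged,
                          iterations = iterations, starved = starved,
                          stringsAsFactors = FALSE))
}
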