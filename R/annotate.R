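#' Read an effector-function annotation TSV
#'
#' Columns \code{effector_gene} and \code{functions} (";"-joined free-text
#' terms).  A packaged example derived from curated effector annotations
#' ships at \code{system.file("extdata", "effector_functions.tsv",
#' package = "sigcircuit")}.
#'
#' @param file path to the TSV.
#' @return named list: effector gene -> character vector of function terms.
#' @export
readFunctionAnnotation <- function(file) {
  df <- .readTsv(file, required = c("effector_gene", "functions"),
                 what = "function annotation")
  stats::setNames(.splitGenes(df$functions), df$effector_gene)
}

#' Read an effector-hallmark map TSV
#'
#' Columns \code{effector_gene} and \code{hallmarks} (";"-joined).  Hallmark
#' names must come from the declared vocabulary (defaults to the canonical
#' ten acquired tumor capabilities).  A constructed demonstration map ships
#' at \code{system.file("extdata", "effector_hallmarks_synthetic.tsv",
#' package = "sigcircuit")}; it is a synthetic stand-in, not a mined
#' literature resource.
#'
#' @param file path to the TSV.
#' @param vocabulary allowed hallmark names.
#' @return named list: effector gene -> character vector of hallmarks.
#' @export
readHallmarkMap <- function(file, vocabulary = hallmarkVocabulary()) {
  df <- .readTsv(file, required = c("effector_gene", "hallmarks"),
                 what = "hallmark map")
  hm <- stats::setNames(.splitGenes(df$hallmarks), df$effector_gene)
  bad <- setdiff(unique(unlist(hm)), vocabulary)
  if (length(bad))
    .formatError("hallmark name(s) outside the declared vocabulary: %s",
                 paste(bad, collapse = "; "))
  hm
}

#' The default cancer-hallmark vocabulary
#'
#' The ten canonical acquired capabilities of tumors.
#' @return character vector of ten hallmark names.
#' @export
hallmarkVocabulary <- function() {
  c("Sustaining proliferative signaling",
    "Evading growth suppressors",
    "Resisting cell death",
    "Enabling replicative immortality",
    "Inducing angiogenesis",
    "Activating invasion and metastasis",
    "Genome instability and mutation",
    "Tumor-promoting inflammation",
    "Deregulating cellular energetics",
    "Avoiding immune destruction")
}

#' Annotate circuits with effector functions and hallmarks
#'
#' Each circuit is keyed by the genes of its effector node: the union of
#' the function terms (and hallmarks) of those genes is attached.  Circuits
#' whose effector genes carry no function annotation get the explicit term
#' \code{"unannotated"}; missing hallmark entries yield an empty hallmark
#' list.  Output order follows the input circuit order.
#'
#' @param circuits list of [Circuit-class].
#' @param functionAnnotation named list from [readFunctionAnnotation()] (or
#'   equivalent gene -> terms list).
#' @param hallmarkMap named list from [readHallmarkMap()]; optional.
#' @return data.frame with columns \code{circuit_id}, \code{pathway_id},
#'   \code{display_name}, \code{effector}, \code{effector_genes},
#'   \code{functions}, \code{hallmarks} (";"-joined).
#' @export
annotateCircuits <- function(circuits, functionAnnotation,
                             hallmarkMap = list()) {
  if (!is.list(functionAnnotation) || is.null(names(functionAnnotation)))
    .formatError("functionAnnotation must be a named list of term vectors")
  effGenes <- lapply(circuits, .effectorGenes)
  lookup <- function(gs, tab) unique(unlist(tab[intersect(gs, names(tab))]))
  fn <- lapply(effGenes, function(gs) {
    t <- lookup(gs, functionAnnotation)
    if (!length(t)) "unannotated" else t
  })
  hm <- lapply(effGenes, function(gs) lookup(gs, hallmarkMap))
  data.frame(
    circuit_id = vapply(circuits, circuitId, character(1)),
    pathway_id = vapply(circuits, pathwayId, character(1)),
    display_name = vapply(circuits, displayName, character(1)),
    effector = vapply(circuits, effector, character(1)),
    effector_genes = vapply(effGenes, paste, character(1), collapse = ";"),
    functions = vapply(fn, paste, character(1), collapse = ";"),
    hallmarks = vapply(hm, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}

# genes of the effector node, stored on the circuit at extraction time;
# gene-free effectors fall back to the node id so lookups stay total
.effectorGenes <- function(circuit) {
  g <- circuit@effectorGenes
  if (length(g)) g else circuit@effector
}

#' Summarize significant circuits by cancer hallmark
#'
#' Counts, per hallmark, the significant circuits whose effector maps to it.
#' A circuit annotated with k hallmarks contributes to all k counts
#' (multi-counting; declared in the \code{"counting"} attribute).  With a
#' named list of result tables, a hallmark-by-condition count matrix is
#' returned.
#'
#' @param results a result data.frame (from [differentialSignaling()] and
#'   friends) or a named list of them (one per condition).
#' @param annotated circuit annotation table from [annotateCircuits()].
#' @param alpha FDR threshold defining "significant".
#' @return data.frame with a \code{hallmark} column and one count column per
#'   condition.
#' @export
hallmarkSummary <- function(results, annotated, alpha = 0.05) {
  if (is.data.frame(results)) results <- list(count = results)
  if (is.null(names(results)))
    names(results) <- paste0("condition", seq_along(results))
  vocab <- hallmarkVocabulary()
  hmPer <- stats::setNames(.splitGenes(annotated$hallmarks),
                           annotated$circuit_id)
  counts <- vapply(results, function(tab) {
    sig <- tab$circuit_id[tab$fdr_p < alpha]
    tallied <- unlist(hmPer[intersect(sig, names(hmPer))])
    vapply(vocab, function(h) sum(tallied == h), numeric(1))
  }, numeric(length(vocab)))
  out <- data.frame(hallmark = vocab, counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counting") <- "multi-count: a circuit with k hallmarks contributes to all k"
  out
}

#' Circuits recurrently significant across conditions
#'
#' Lists every circuit significant (FDR < alpha) in at least
#' \code{minConditions} of the supplied conditions, with the conditions
#' where it is significant, sorted by count descending then circuit id.
#'
#' @param resultsList named list of result tables, one per condition.
#' @param minConditions minimum number of conditions (default 4).
#' @param alpha FDR threshold.
#' @return data.frame with columns \code{circuit_id}, \code{n_conditions},
#'   \code{conditions} (";"-joined).
#' @export
pervasiveness <- function(resultsList, minConditions = 4L, alpha = 0.05) {
  if (!length(resultsList)) .inputError("at least one condition required")
  if (is.null(names(resultsList)))
    names(resultsList) <- paste0("condition", seq_along(resultsList))
  sigSets <- lapply(resultsList, function(tab)
    tab$circuit_id[tab$fdr_p < alpha])
  all <- sort(unique(unlist(sigSets)))
  conds <- lapply(all, function(cid)
    names(sigSets)[vapply(sigSets, function(s) cid %in% s, logical(1))])
  n <- lengths(conds)
  keep <- n >= minConditions
  out <- data.frame(circuit_id = all[keep], n_conditions = n[keep],
                    conditions = vapply(conds[keep], paste, character(1),
                                        collapse = ";"),
                    stringsAsFactors = FALSE)
  out[order(-out$n_conditions, out$circuit_id), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}
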