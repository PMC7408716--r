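#' Build a pipeline run configuration
#'
#' Collects input paths and tunables for [runPipeline()].  Any unset
#' optional input (drugs, annotations) simply skips the corresponding
#' stage.
#'
#' @param nodes,edges paths to the pathway node/edge TSVs (may carry a
#'   \code{pathway_id} column for multi-pathway files).
#' @param expr path to the raw expression TSV.
#' @param labels path to the sample_id/group TSV.
#' @param outDir output directory.
#' @param drugs optional drug TSV path.
#' @param functions,hallmarks optional annotation TSV paths.
#' @param quantileQ upper-truncation quantile.
#' @param rule gene-to-node aggregation rule.
#' @param tol,maxIter fixed-point controls for cyclic circuits.
#' @param knockdownValue drug knockdown value on the unit scale.
#' @param epsilonFc additive stabilizer for drug log2 fold changes.
#' @param alpha FDR threshold.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when inputs were generated upstream).
#' @return a \code{runConfig} list.
#' @export
runConfig <- function(nodes, edges, expr, labels, outDir,
                      drugs = NULL, functions = NULL, hallmarks = NULL,
                      quantileQ = 0.99, rule = "mean", tol = 1e-6,
                      maxIter = 100L, knockdownValue = 0.001,
                      epsilonFc = 1e-6, alpha = 0.05, seed = 1L) {
  structure(list(nodes = nodes, edges = edges, expr = expr,
                 labels = labels, outDir = outDir, drugs = drugs,
                 functions = functions, hallmarks = hallmarks,
                 quantileQ = quantileQ, rule = rule, tol = tol,
                 maxIter = as.integer(maxIter),
                 knockdownValue = knockdownValue, epsilonFc = epsilonFc,
                 alpha = alpha, seed = as.integer(seed)),
            class = "runConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full circuit-activity pipeline
#'
#' Executes: load pathways -> normalize expression (log2, quantile
#' truncation, unit scaling) -> node values -> circuit extraction ->
#' activity propagation -> two-group differential signaling -> per drug:
#' knockdown simulation, paired test, group-differential fold-change test ->
#' annotation summaries.  All intermediate and final tables are written as
#' TSV under \code{outDir}, together with \code{manifest.json} (resolved
#' config, package version, timings).  Reruns with identical inputs and
#' config produce byte-identical result TSVs.
#'
#' @param config a [runConfig()] list.
#' @return invisible list of the in-memory results (circuits, activity,
#'   gsdsa table, per-drug tables, annotation tables).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  t0 <- Sys.time()
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  graphs <- .stage("load_pathways",
                   loadPathways(config$nodes, config$edges))
  labels <- .stage("load_labels", readLabels(config$labels))
  exprRaw <- .stage("load_expression", readExpression(config$expr))

  exprUnit <- .stage("normalize", {
    scaleUnit(truncateQuantile(logTransform(exprRaw), q = config$quantileQ))
  })
  nv <- .stage("node_values", nodeValues(exprUnit, graphs,
                                         rule = config$rule))
  circuits <- .stage("circuits", unlist(lapply(graphs,
                                               extractEffectorCircuits),
                                        recursive = FALSE))
  act <- .stage("activity",
                computeActivityMatrix(circuits, nv, tol = config$tol,
                                      maxIter = config$maxIter))
  gsdsa <- .stage("differential_signaling",
                  differentialSignaling(act, labels, alpha = config$alpha))

  out <- function(f) file.path(config$outDir, f)
  circuitTable(circuits, out("circuits.tsv"))
  .writeTsv(nv@flags, out("node_flags.tsv"))
  .writeMatrixTsv(act@activity, out("activity.tsv"), "circuit_id")
  .writeTsv(act@report, out("convergence.tsv"))
  .writeTsv(gsdsa, out("gsdsa.tsv"))

  drugResults <- list()
  if (!is.null(config$drugs)) {
    drugs <- .stage("load_drugs",
                    readDrugTable(config$drugs,
                                  knockdownValue = config$knockdownValue))
    for (d in drugs) {
      nm <- drugName(d)
      sim <- .stage(paste0("simulate_drug:", nm),
                    simulateDrug(circuits, graphs, exprUnit, d,
                                 rule = config$rule,
                                 epsilon = config$epsilonFc,
                                 tol = config$tol,
                                 maxIter = config$maxIter))
      paired <- .stage(paste0("paired_test:", nm),
                       pairedDrugTest(sim$ref, sim$trt,
                                      alpha = config$alpha))
      fcSplit <- splitFoldChanges(sim$fc, labels)
      diffEff <- .stage(paste0("differential_drug_effect:", nm),
                        differentialDrugEffect(fcSplit[[1]], fcSplit[[2]],
                                               groups = names(fcSplit),
                                               alpha = config$alpha))
      safe <- gsub("[^A-Za-z0-9_.-]", "_", nm)
      .writeMatrixTsv(sim$fc@fc, out(paste0(safe, "_fc.tsv")), "circuit_id")
      .writeTsv(paired, out(paste0(safe, "_paired.tsv")))
      .writeTsv(diffEff, out(paste0(safe, "_diff_effect.tsv")))
      drugResults[[nm]] <- list(sim = sim, paired = paired,
                                diffEffect = diffEff)
    }
  }

  annotated <- NULL
  hallmarks <- NULL
  if (!is.null(config$functions)) {
    fa <- .stage("load_annotation", readFunctionAnnotation(config$functions))
    hm <- if (!is.null(config$hallmarks))
      .stage("load_hallmarks", readHallmarkMap(config$hallmarks))
    else list()
    annotated <- .stage("annotate", annotateCircuits(circuits, fa, hm))
    .writeTsv(annotated, out("annotated_circuits.tsv"))
    if (length(hm)) {
      hallmarks <- hallmarkSummary(gsdsa, annotated, alpha = config$alpha)
      .writeTsv(hallmarks, out("hallmark_summary.tsv"))
    }
  }

  manifest <- list(
    package = "sigcircuit",
    version = as.character(utils::packageVersion("sigcircuit")),
    config = unclass(config),
    n_pathways = length(graphs),
    n_circuits = length(circuits),
    n_samples = ncol(exprRaw@values),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  invisible(list(graphs = graphs, circuits = circuits, activity = act,
                 gsdsa = gsdsa, drugs = drugResults,
                 annotated = annotated, hallmarkSummary = hallmarks))
}
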