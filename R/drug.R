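#' Construct a drug specification
#'
#' @param drugName drug label.
#' @param targets non-empty character vector of target gene symbols.
#' @param knockdownValue value in (0, 1) substituted for target-gene
#'   expression on the unit scale; default 0.001, a near-zero value that
#'   keeps a basal activity in the circuit rather than an absolute zero.
#' @return a [DrugSpec-class].
#' @export
drugSpec <- function(drugName, targets, knockdownValue = 0.001) {
  new("DrugSpec", drugName = as.character(drugName),
      targets = as.character(targets),
      knockdownValue = as.numeric(knockdownValue))
}

#' Read a drug table TSV (columns drug_name, targets with ";"-joined genes)
#' @param file path.
#' @param knockdownValue knockdown value applied to every drug.
#' @return named list of [DrugSpec-class].
#' @export
readDrugTable <- function(file, knockdownValue = 0.001) {
  df <- .readTsv(file, required = c("drug_name", "targets"), what = "drug")
  drugs <- lapply(seq_len(nrow(df)), function(i)
    drugSpec(df$drug_name[i],
             .splitGenes(df$targets[i])[[1]],
             knockdownValue = knockdownValue))
  stats::setNames(drugs, df$drug_name)
}

#' Apply an in-silico knockdown to a unit-scaled expression matrix
#'
#' Every target gene present in the matrix has its value replaced, in all
#' samples, by the drug's knockdown value; all other genes are untouched.
#' Targets absent from the matrix are reported in a warning (and in the
#' \code{"absent_targets"} attribute); if no target is present at all the
#' simulation is meaningless and an input error names the drug.
#'
#' @param m a unit-scale [GeneExpressionMatrix-class].
#' @param drug a [DrugSpec-class].
#' @return the pseudo-treated matrix, scale \code{"unit"}.
#' @export
applyKnockdown <- function(m, drug) {
  stopifnot(is(m, "GeneExpressionMatrix"), is(drug, "DrugSpec"))
  if (m@scale != "unit")
    .domainError("applyKnockdown expects scale 'unit', got '%s'", m@scale)
  present <- intersect(drug@targets, rownames(m@values))
  absent <- setdiff(drug@targets, rownames(m@values))
  if (!length(present))
    .inputError("drug '%s': none of its target genes (%s) are in the matrix",
                drug@drugName, paste(drug@targets, collapse = ", "))
  if (length(absent))
    warning(sprintf("drug '%s': target gene(s) not in the matrix: %s",
                    drug@drugName, paste(absent, collapse = ", ")))
  v <- m@values
  v[present, ] <- drug@knockdownValue
  out <- geneExpression(v, scale = "unit")
  attr(out, "absent_targets") <- absent
  out
}

#' Simulate a drug intervention on circuit activities
#'
#' Computes reference circuit activities from the untouched unit-scale
#' expression, pseudo-treated activities after knocking the drug's target
#' genes down, and the per-patient log2 fold-change matrix
#' \code{log2((treated + eps) / (reference + eps))}.  Reference and treated
#' matrices share circuit and sample order.
#'
#' @param circuits list of [Circuit-class].
#' @param graphs [PathwayGraph-class] or list of them (for node
#'   aggregation).
#' @param m unit-scale [GeneExpressionMatrix-class].
#' @param drug a [DrugSpec-class].
#' @param rule gene-to-node aggregation rule, see [nodeValues()].
#' @param epsilon additive stabilizer for the log-ratio.
#' @param ... passed to [computeActivityMatrix()] (\code{tol},
#'   \code{maxIter}, \code{initialSignal}).
#' @return list with elements \code{ref} and \code{trt}
#'   ([CircuitActivityMatrix-class]) and \code{fc}
#'   ([FoldChangeMatrix-class]).
#' @export
simulateDrug <- function(circuits, graphs, m, drug, rule = "mean",
                         epsilon = 1e-6, ...) {
  stopifnot(is(drug, "DrugSpec"))
  ref <- computeActivityMatrix(circuits, nodeValues(m, graphs, rule = rule),
                               ...)
  treatedExpr <- applyKnockdown(m, drug)
  trt <- computeActivityMatrix(circuits,
                               nodeValues(treatedExpr, graphs, rule = rule),
                               ...)
  fc <- log2((trt@activity + epsilon) / (ref@activity + epsilon))
  list(ref = ref, trt = trt,
       fc = new("FoldChangeMatrix", fc = fc, epsilon = epsilon))
}

#' Paired test of treated versus reference circuit activity
#'
#' Per circuit, a two-sided Wilcoxon signed-rank test on the paired
#' (reference, pseudo-treated) activities of the same patients, with
#' Benjamini-Hochberg correction across circuits.  Zero differences are
#' dropped per the signed-rank convention; a circuit untouched by the drug
#' in every patient gets p = 1.
#'
#' @param ref,trt [CircuitActivityMatrix-class] objects of identical shape
#'   and identical circuit/sample order.
#' @param alpha FDR threshold for the \code{significant} flag.
#' @return data.frame with columns \code{circuit_id}, \code{statistic} (V),
#'   \code{p_value}, \code{fdr_p}, \code{mean_g1} (reference),
#'   \code{mean_g2} (treated), \code{direction}, \code{significant};
#'   groups attribute is \code{c("ref", "trt")}.
#' @export
pairedDrugTest <- function(ref, trt, alpha = 0.05) {
  stopifnot(is(ref, "CircuitActivityMatrix"),
            is(trt, "CircuitActivityMatrix"))
  if (!identical(dimnames(ref@activity), dimnames(trt@activity)))
    .inputError("reference and treated matrices must share circuit and sample order")
  if (ncol(ref@activity) < 2L)
    .inputError("paired test needs >= 2 samples")
  r <- ref@activity; t <- trt@activity
  n <- nrow(r)
  stat <- p <- numeric(n)
  for (k in seq_len(n)) {
    wt <- wilcoxonSignedRank(r[k, ], t[k, ])
    stat[k] <- wt$statistic; p[k] <- wt$p.value
  }
  res <- data.frame(circuit_id = rownames(r), statistic = stat,
                    p_value = p, fdr_p = benjaminiHochberg(p),
                    mean_g1 = rowMeans(r), mean_g2 = rowMeans(t),
                    stringsAsFactors = FALSE)
  res$significant <- res$fdr_p < alpha
  res$direction <- .assignDirection(res, c("ref", "trt"))
  rownames(res) <- NULL
  attr(res, "groups") <- c("ref", "trt")
  res
}

#' Group-differential drug effect on circuit fold changes
#'
#' Compares the per-patient log2 fold-change distributions of two patient
#' groups circuit by circuit: reports the mean fold change per group and
#' their difference (the direct comparison), plus a two-sided Wilcoxon
#' rank-sum significance assessment with Benjamini-Hochberg correction.
#'
#' @param fcG1,fcG2 [FoldChangeMatrix-class] objects with identical circuit
#'   order; each with at least two samples.
#' @param groups length-2 character, names for the two groups.
#' @param alpha FDR threshold.
#' @return data.frame with columns \code{circuit_id}, \code{statistic},
#'   \code{p_value}, \code{fdr_p}, \code{mean_g1}, \code{mean_g2} (mean fold
#'   change per group), \code{mean_diff}, \code{direction},
#'   \code{significant}.
#' @export
differentialDrugEffect <- function(fcG1, fcG2, groups = c("G1", "G2"),
                                   alpha = 0.05) {
  stopifnot(is(fcG1, "FoldChangeMatrix"), is(fcG2, "FoldChangeMatrix"))
  f1 <- fcG1@fc; f2 <- fcG2@fc
  if (!identical(rownames(f1), rownames(f2)))
    .inputError("fold-change matrices must share circuit order")
  if (ncol(f1) < 2L || ncol(f2) < 2L)
    .inputError("each group needs >= 2 samples")
  n <- nrow(f1)
  stat <- p <- numeric(n)
  for (k in seq_len(n)) {
    x <- f1[k, ]; y <- f2[k, ]
    if (max(c(x, y)) == min(c(x, y))) {   # no variation at all: no evidence
      stat[k] <- NA_real_; p[k] <- 1
    } else {
      wt <- wilcoxonRankSum(x, y)
      stat[k] <- wt$statistic; p[k] <- wt$p.value
    }
  }
  res <- data.frame(circuit_id = rownames(f1), statistic = stat,
                    p_value = p, fdr_p = benjaminiHochberg(p),
                    mean_g1 = rowMeans(f1), mean_g2 = rowMeans(f2),
                    stringsAsFactors = FALSE)
  res$mean_diff <- res$mean_g1 - res$mean_g2
  res$significant <- res$fdr_p < alpha
  res$direction <- .assignDirection(res, groups)
  rownames(res) <- NULL
  attr(res, "groups") <- groups
  res
}

#' Split a fold-change matrix by sample group
#' @param fc a [FoldChangeMatrix-class].
#' @param labels named group labels covering the samples (two groups).
#' @return named list of two [FoldChangeMatrix-class], in level order.
#' @export
splitFoldChanges <- function(fc, labels) {
  stopifnot(is(fc, "FoldChangeMatrix"))
  labels <- .checkLabels(labels, colnames(fc@fc))
  out <- lapply(levels(labels), function(g)
    new("FoldChangeMatrix",
        fc = fc@fc[, labels == g, drop = FALSE], epsilon = fc@epsilon))
  stats::setNames(out, levels(labels))
}
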