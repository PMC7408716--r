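#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Thin wrapper over the standard two-sample Wilcoxon test with the policy
#' fixed: the exact null distribution is used when the pooled size is at
#' most 20 and there are no ties; otherwise the normal approximation with
#' tie and continuity correction.  Returns the Mann-Whitney U statistic of
#' \code{x} versus \code{y}.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param alternative \code{"two.sided"} (default), \code{"less"},
#'   \code{"greater"}.
#' @return list with elements \code{statistic} (U) and \code{p.value}.
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))$p.value  # 1/3
#' @export
wilcoxonRankSum <- function(x, y,
                            alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y))
    .inputError("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Paired variant used to compare pseudo-treated against reference activity
#' profiles of the same patients.  Zero differences are dropped per the
#' standard signed-rank convention; if every pair ties, p = 1 by convention.
#' Exact null distribution when there are at most 20 non-zero untied
#' differences, normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric vectors of equal length (paired observations).
#' @param alternative as in [wilcoxonRankSum()].
#' @return list with elements \code{statistic} (V, the positive-rank sum)
#'   and \code{p.value}.
#' @export
wilcoxonSignedRank <- function(x, y,
                               alternative = c("two.sided", "less",
                                               "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y))
    .inputError("paired vectors must have equal length")
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    return(list(statistic = NA_real_, p.value = 1))
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- !ties && length(d) <= 20L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted values in the input order, capped at 1.
#' @export
benjaminiHochberg <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    .inputError("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential circuit activity (the GS-DSA test)
#'
#' For every circuit, activities are split by group label and compared with
#' a two-sided Wilcoxon rank-sum test; p-values are Benjamini-Hochberg
#' adjusted jointly across all tested circuits.  Circuits with zero variance
#' across all samples carry no rank information and are excluded before
#' testing (listed in the \code{"excluded"} attribute).  Direction is
#' assigned post hoc from the group means at \code{fdr_p < alpha}.
#'
#' @param act a [CircuitActivityMatrix-class].
#' @param labels named character/factor: sample id -> group, covering every
#'   sample column; exactly two groups, each with at least two samples.
#' @param alpha FDR threshold for the \code{significant} flag.
#' @return data.frame with columns \code{circuit_id}, \code{statistic},
#'   \code{p_value}, \code{fdr_p}, \code{mean_g1}, \code{mean_g2},
#'   \code{direction} (\code{"<g1>><g2>"}, \code{"<g2>><g1>"} or
#'   \code{"none"}), \code{significant}; group order follows factor levels.
#'   Attributes: \code{groups}, \code{excluded}.
#' @export
differentialSignaling <- function(act, labels, alpha = 0.05) {
  stopifnot(is(act, "CircuitActivityMatrix"))
  a <- act@activity
  labels <- .checkLabels(labels, colnames(a))
  g <- levels(labels)
  n1 <- sum(labels == g[1]); n2 <- sum(labels == g[2])
  if (n1 < 2L || n2 < 2L)
    .inputError("each group needs >= 2 samples (got %d and %d)", n1, n2)

  spread <- apply(a, 1L, function(r) max(r) - min(r))
  excluded <- rownames(a)[spread == 0]
  keep <- rownames(a)[spread > 0]
  res <- .rowWiseRankSum(a[keep, , drop = FALSE], labels, g)
  res$fdr_p <- benjaminiHochberg(res$p_value)
  res$significant <- res$fdr_p < alpha
  res$direction <- .assignDirection(res, g)
  res <- res[, c("circuit_id", "statistic", "p_value", "fdr_p",
                 "mean_g1", "mean_g2", "direction", "significant")]
  attr(res, "groups") <- g
  attr(res, "excluded") <- excluded
  res
}

.checkLabels <- function(labels, samples) {
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "group") %in% colnames(labels)))
      .formatError("labels table needs columns sample_id and group")
    labels <- stats::setNames(labels$group, labels$sample_id)
  }
  if (is.null(names(labels)))
    .inputError("labels must be named by sample id")
  missing <- setdiff(samples, names(labels))
  if (length(missing))
    .inputError("no group label for sample(s): %s",
                paste(missing, collapse = ", "))
  labels <- factor(as.character(labels[samples]))
  if (nlevels(labels) != 2L)
    .inputError("exactly two groups required, got %d (%s)",
                nlevels(labels), paste(levels(labels), collapse = ", "))
  labels
}

.rowWiseRankSum <- function(a, labels, g) {
  i1 <- labels == g[1]; i2 <- labels == g[2]
  n <- nrow(a)
  stat <- p <- m1 <- m2 <- numeric(n)
  for (k in seq_len(n)) {
    x <- a[k, i1]; y <- a[k, i2]
    wt <- wilcoxonRankSum(x, y)
    stat[k] <- wt$statistic; p[k] <- wt$p.value
    m1[k] <- mean(x); m2[k] <- mean(y)
  }
  data.frame(circuit_id = rownames(a), statistic = stat, p_value = p,
             mean_g1 = m1, mean_g2 = m2, stringsAsFactors = FALSE)
}

.assignDirection <- function(res, g) {
  ifelse(!res$significant, "none",
         ifelse(res$mean_g1 > res$mean_g2,
                paste0(g[1], ">", g[2]), paste0(g[2], ">", g[1])))
}

#' Count significant circuits by direction
#'
#' @param tab a result table from [differentialSignaling()],
#'   [pairedDrugTest()] or [differentialDrugEffect()].
#' @param alpha FDR threshold.
#' @return named numeric vector \code{c(n_total, n_g1_up, n_g2_up)}; the up
#'   counts follow the group order stored in the table's \code{groups}
#'   attribute (group-1-higher first).
#' @export
countSignificant <- function(tab, alpha = 0.05) {
  sig <- tab$fdr_p < alpha
  up1 <- sig & tab$mean_g1 > tab$mean_g2
  up2 <- sig & tab$mean_g2 > tab$mean_g1
  c(n_total = sum(up1) + sum(up2), n_g1_up = sum(up1), n_g2_up = sum(up2))
}

#' Read a sample-to-group labels TSV (columns sample_id, group)
#' @param file path.
#' @return named factor.
#' @export
readLabels <- function(file) {
  df <- .readTsv(file, required = c("sample_id", "group"), what = "labels")
  factor(stats::setNames(as.character(df$group), df$sample_id))
}
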