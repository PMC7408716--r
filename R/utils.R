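.condition <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "sigcircuitError", "error")))
}

# condition classes mirror the failure modes of the input contracts:
# format (malformed table), integrity (inconsistent graph), structural
# (no receptor/effector derivable), input (bad arguments), domain (value range)
.formatError     <- function(fmt, ...) .condition("sc_format_error", fmt, ...)
.integrityError  <- function(fmt, ...) .condition("sc_integrity_error", fmt, ...)
.structuralError <- function(fmt, ...) .condition("sc_structural_error", fmt, ...)
.inputError      <- function(fmt, ...) .condition("sc_input_error", fmt, ...)
.domainError     <- function(fmt, ...) .condition("sc_domain_error", fmt, ...)

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.readTsv <- function(path, required = character(), what = "table") {
  if (!file.exists(path))
    .inputError("%s file not found: '%s'", what, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    .formatError("%s file '%s' lacks required column(s): %s",
                 what, path, paste(missing, collapse = ", "))
  df
}

# matrix -> long-form TSV with an id first column (round-trips via .readMatrixTsv)
.writeMatrixTsv <- function(m, path, idCol) {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(idCol, colnames(m))
  .writeTsv(df, path)
}

.readMatrixTsv <- function(path, what = "matrix") {
  df <- .readTsv(path, what = what)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

.splitGenes <- function(x, delim = ";") {
  out <- strsplit(as.character(x), delim, fixed = TRUE)
  lapply(out, function(g) {
    g <- trimws(g)
    g[nzchar(g)]
  })
}

.joinGenes <- function(genes, delim = ";") {
  vapply(genes, paste, character(1), collapse = delim)
}

# seeded evaluation that leaves the caller's RNG stream untouched
.withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}
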