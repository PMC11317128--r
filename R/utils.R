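# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation failures (bad user input) are signalled with a dedicated condition
# class so callers (and the CLI) can distinguish them from computation errors.
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("deconcord_validation_error", "validationError")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("deconcord_format_error", "formatError")))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# Unbiased per-row standard deviations without a matrixStats dependency.
row_sds <- function(x) {
  n <- ncol(x)
  if (n < 2L) stop_validation("row_sds needs at least two columns")
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1L))
}

assert_count_matrix <- function(counts, allow_duplicates = FALSE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_validation("counts must be a numeric matrix (genes x samples)")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop_validation("count matrix is empty")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_validation("count matrix needs gene row names and sample column names")
  if (anyNA(counts)) stop_validation("count matrix contains missing values")
  if (any(counts < 0)) stop_validation("count matrix contains negative values")
  if (!is_wholenumber(counts)) stop_validation("count matrix must hold integral counts")
  if (anyDuplicated(colnames(counts)))
    stop_format("duplicate sample ids in count matrix")
  if (!allow_duplicates && anyDuplicated(rownames(counts)))
    stop_validation("duplicate gene ids; aggregate with aggregate_gene_ids() first")
  invisible(counts)
}

assert_sample_sheet <- function(samples, counts = NULL) {
  if (!is.data.frame(samples) || !all(c("sample", "group") %in% names(samples)))
    stop_validation("sample sheet must be a data.frame with 'sample' and 'group' columns")
  if (anyDuplicated(samples$sample))
    stop_validation("duplicate sample ids in sample sheet")
  if (anyNA(samples$group))
    stop_validation("every sample needs a group label")
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts), samples$sample)
    if (length(missing))
      stop_validation("samples missing from sample sheet: %s",
                      paste(missing, collapse = ", "))
  }
  invisible(samples)
}

# Align a sample sheet to the column order of a count matrix.
align_samples <- function(samples, counts) {
  assert_sample_sheet(samples, counts)
  samples[match(colnames(counts), samples$sample), , drop = FALSE]
}
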