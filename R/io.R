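#' Read a gene x sample count matrix
#'
#' Reads a delimited text file whose first column holds gene identifiers and
#' whose remaining columns hold non-negative integer counts, one column per
#' sample. Duplicate gene identifiers are tolerated at this stage (they occur
#' when several source identifiers map to one symbol) and are flagged so they
#' can be collapsed with [aggregate_gene_ids()]; duplicate sample identifiers
#' are a format error.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field separator, `"\t"` by default.
#' @return An integer matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names. Library sizes are the column sums.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "g1\t3\t4", "g2\t0\t2"), tf)
#' m <- read_count_matrix(tf)
#' colSums(m)
#' @export
read_count_matrix <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, quote = "",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop_format("count file needs a gene column plus sample columns")
  ids <- as.character(tab[[1L]])
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids))
    stop_format("duplicate sample ids in header: %s",
                paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_validation("non-numeric count columns")
  if (anyNA(vals)) stop_validation("missing values in counts")
  if (any(vals < 0)) stop_validation("negative counts in %s", path)
  if (!is_wholenumber(vals)) stop_validation("non-integral counts in %s", path)
  m <- matrix(as.integer(round(vals)), nrow = nrow(vals),
              dimnames = list(ids, sample_ids))
  attr(m, "duplicated_gene_ids") <- anyDuplicated(ids) > 0L
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Matrix as returned by [read_count_matrix()].
#' @param path Output file.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, delimiter = "\t") {
  tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  utils::write.table(tab, path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' A sample sheet assigns each sample to exactly one experimental group and
#' may carry additional categorical covariate columns.
#'
#' @param path TSV with at least columns `sample` and `group`.
#' @param delimiter Field separator.
#' @return A data.frame with columns `sample`, `group`, plus any covariates.
#' @export
read_sample_sheet <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE)
  assert_sample_sheet(tab)
  tab$sample <- as.character(tab$sample)
  tab$group <- as.character(tab$group)
  tab
}

#' Sum counts of gene identifiers that map to the same target id
#'
#' When several source identifiers point at the same gene symbol, their count
#' rows are summed element-wise so that each output identifier is unique.
#' Column (per-sample) totals are conserved exactly.
#'
#' @param counts Matrix (genes x samples); duplicate row names allowed.
#' @param id_map Named character vector mapping every input gene id to its
#'   target id. Defaults to the identity map on the row names, which collapses
#'   rows that already share an identifier.
#' @return Matrix with unique row names, rows summed within target id, target
#'   ids ordered by first occurrence.
#' @export
aggregate_gene_ids <- function(counts, id_map = NULL) {
  if (!is.matrix(counts) || nrow(counts) == 0L)
    stop_validation("empty count matrix")
  ids <- rownames(counts)
  if (is.null(ids)) stop_validation("count matrix needs gene row names")
  if (is.null(id_map)) {
    new_ids <- ids
  } else {
    if (is.null(names(id_map))) stop_validation("id_map must be a named vector")
    uncovered <- setdiff(ids, names(id_map))
    if (length(uncovered))
      stop_validation("id_map does not cover: %s",
                      paste(utils::head(uncovered, 5L), collapse = ", "))
    new_ids <- unname(id_map[ids])
  }
  out <- rowsum(counts, group = new_ids, reorder = FALSE)
  storage.mode(out) <- "integer"
  out
}

#' Drop small groups and down-sample the rest to a common size
#'
#' Groups with fewer than `min_size` samples are removed; every surviving
#' group is down-sampled without replacement to `target_size` samples so that
#' group sizes do not drive between-group comparisons. The subsampling is
#' deterministic given `seed`.
#'
#' @param samples Sample sheet data.frame (`sample`, `group`, ...).
#' @param min_size Minimum group size to keep a group.
#' @param target_size Number of samples to retain per surviving group; must
#'   not exceed `min_size`.
#' @param seed Integer seed for the subsampling.
#' @return The balanced sample sheet (row order: groups alphabetically,
#'   samples in input order within group).
#' @export
balance_groups <- function(samples, min_size, target_size = min_size, seed = 1L) {
  assert_sample_sheet(samples)
  if (target_size > min_size)
    stop_validation("target_size (%d) must be <= min_size (%d)", target_size, min_size)
  sizes <- table(samples$group)
  keep_groups <- names(sizes)[sizes >= min_size]
  if (!length(keep_groups)) stop_validation("no group has >= %d samples", min_size)
  set.seed(seed)
  picked <- lapply(sort(keep_groups), function(g) {
    rows <- which(samples$group == g)
    sort(sample(rows, target_size))
  })
  out <- samples[unlist(picked), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate group contrasts
#'
#' Builds the table of comparisons to test. By default all non-redundant
#' pairwise comparisons are generated, ordered lexicographically (the
#' alphabetically smaller group is the numerator) so results are stable
#' across runs; effect sizes downstream follow the numerator - denominator
#' sign convention. `one-vs-rest` compares each group against the pooled
#' remaining groups (`denominator = "rest"`), and `vs-reference` compares
#' every other group against a fixed reference.
#'
#' @param samples Sample sheet.
#' @param user_list Optional data.frame with columns `numerator` and
#'   `denominator` naming the comparisons explicitly.
#' @param mode One of `"all-pairwise"`, `"vs-reference"`, `"one-vs-rest"`.
#' @param reference Reference group (required for `vs-reference`).
#' @param block Optional covariate column name; contrasts are enumerated
#'   within each level of the blocking covariate.
#' @return data.frame with columns `id`, `numerator`, `denominator` (and
#'   `block` when blocking is used).
#' @export
enumerate_contrasts <- function(samples, user_list = NULL,
                                mode = c("all-pairwise", "vs-reference", "one-vs-rest"),
                                reference = NULL, block = NULL) {
  mode <- match.arg(mode)
  assert_sample_sheet(samples)
  make_id <- function(num, den) paste0(num, "_vs_", den)
  if (!is.null(user_list)) {
    if (!all(c("numerator", "denominator") %in% names(user_list)))
      stop_validation("user contrast list needs 'numerator' and 'denominator' columns")
    groups <- unique(samples$group)
    named <- unique(c(user_list$numerator,
                      setdiff(user_list$denominator, "rest")))
    missing <- setdiff(named, groups)
    if (length(missing))
      stop_validation("contrast list names unknown groups: %s",
                      paste(missing, collapse = ", "))
    if (any(user_list$numerator == user_list$denominator))
      stop_validation("numerator and denominator must differ")
    return(data.frame(id = make_id(user_list$numerator, user_list$denominator),
                      numerator = as.character(user_list$numerator),
                      denominator = as.character(user_list$denominator),
                      stringsAsFactors = FALSE))
  }
  enumerate_block <- function(sheet, blk) {
    groups <- sort(unique(sheet$group))
    if (length(groups) < 2L)
      stop_validation("need at least two groups to form contrasts")
    res <- switch(mode,
      "all-pairwise" = {
        pairs <- utils::combn(groups, 2L)
        data.frame(numerator = pairs[1L, ], denominator = pairs[2L, ],
                   stringsAsFactors = FALSE)
      },
      "vs-reference" = {
        if (is.null(reference)) stop_validation("vs-reference mode needs a reference group")
        if (!reference %in% groups)
          stop_validation("reference group '%s' not present", reference)
        data.frame(numerator = setdiff(groups, reference),
                   denominator = reference, stringsAsFactors = FALSE)
      },
      "one-vs-rest" = data.frame(numerator = groups, denominator = "rest",
                                 stringsAsFactors = FALSE))
    res$id <- make_id(res$numerator, res$denominator)
    if (!is.null(blk)) {
      res$block <- blk
      res$id <- paste(res$id, blk, sep = "@")
    }
    res[, c("id", "numerator", "denominator", if (!is.null(blk)) "block")]
  }
  if (is.null(block)) return(enumerate_block(samples, NULL))
  if (!block %in% names(samples))
    stop_validation("blocking covariate '%s' not in sample sheet", block)
  out <- lapply(sort(unique(samples[[block]])), function(b)
    enumerate_block(samples[samples[[block]] == b, , drop = FALSE], b))
  do.call(rbind, out)
}
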