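#' Spearman rank correlation between two scored item lists
#'
#' Computed on the intersection of item ids, with average ranks for ties.
#'
#' @param a,b Named numeric vectors of scores.
#' @return Spearman rho, or `NA` with a warning when fewer than 3 shared
#'   items exist.
#' @export
rank_correlation <- function(a, b) {
  if (is.null(names(a)) || is.null(names(b)))
    stop_validation("score vectors must be named by item id")
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3L) {
    warning("fewer than 3 shared items; correlation skipped")
    return(NA_real_)
  }
  stats::cor(a[shared], b[shared], method = "spearman")
}

unordered_pairs <- function(ids) {
  ids <- sort(unique(ids))
  if (length(ids) < 2L) stop_validation("need at least two pipelines")
  utils::combn(ids, 2L)
}

#' Pairwise-pipeline rank-correlation records
#'
#' For every contrast and unordered pipeline pair, Spearman rho is computed in
#' gene space (on the per-gene t-like statistics, over the genes the two
#' pipelines share) and in gene-set space (on the enrichment scores, per
#' resource).
#'
#' @param act Activity table from [enrich_all()] (used for set space).
#' @param de DE table from [run_pipeline_grid()] (used for gene space).
#' @param spaces Subset of `c("gene", "set")`.
#' @return data.frame: `pipeline_a`, `pipeline_b`, `contrast`, `space`,
#'   `resource` (`"genes"` in gene space), `metric = "spearman"`, `value`.
#' @export
consistency_matrix <- function(act = NULL, de = NULL, spaces = c("gene", "set")) {
  spaces <- match.arg(spaces, several.ok = TRUE)
  out <- list()
  add <- function(pa, pb, contrast, space, resource, value) {
    out[[length(out) + 1L]] <<- data.frame(
      pipeline_a = pa, pipeline_b = pb, contrast = contrast, space = space,
      resource = resource, metric = "spearman", value = value,
      stringsAsFactors = FALSE)
  }
  if ("gene" %in% spaces) {
    if (is.null(de)) stop_validation("gene space requires the DE table")
    for (ct in sort(unique(de$contrast))) {
      d <- de[de$contrast == ct, ]
      pairs <- unordered_pairs(d$pipeline)
      scores <- lapply(split(d, d$pipeline), function(x)
        stats::setNames(x$stat, x$gene))
      for (k in seq_len(ncol(pairs)))
        add(pairs[1L, k], pairs[2L, k], ct, "gene", "genes",
            rank_correlation(scores[[pairs[1L, k]]], scores[[pairs[2L, k]]]))
    }
  }
  if ("set" %in% spaces) {
    if (is.null(act)) stop_validation("set space requires the activity table")
    for (res_name in sort(unique(act$resource))) {
      ar <- act[act$resource == res_name, ]
      for (ct in sort(unique(ar$contrast))) {
        d <- ar[ar$contrast == ct, ]
        pairs <- unordered_pairs(d$pipeline)
        scores <- lapply(split(d, d$pipeline), function(x)
          stats::setNames(x$score, x$set))
        for (k in seq_len(ncol(pairs)))
          add(pairs[1L, k], pairs[2L, k], ct, "set", res_name,
              rank_correlation(scores[[pairs[1L, k]]], scores[[pairs[2L, k]]]))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate consistency records
#'
#' Unweighted means over contrasts per pipeline pair, and per pipeline (mean
#' of the pairs it participates in), within each space/resource/metric.
#'
#' @param records Output of [consistency_matrix()] or [similarity_matrix()].
#' @return list with `per_pair` and `per_pipeline` data.frames.
#' @export
aggregate_consistency <- function(records) {
  per_pair <- stats::aggregate(
    value ~ pipeline_a + pipeline_b + space + resource + metric,
    data = records, FUN = mean, na.rm = TRUE)
  long <- rbind(
    data.frame(pipeline = per_pair$pipeline_a, per_pair[, -(1:2)]),
    data.frame(pipeline = per_pair$pipeline_b, per_pair[, -(1:2)]))
  per_pipeline <- stats::aggregate(value ~ pipeline + space + resource + metric,
                                   data = long, FUN = mean, na.rm = TRUE)
  list(per_pair = per_pair, per_pipeline = per_pipeline)
}

#' Top/bottom overlap similarity between two rankings
#'
#' `(|top_N(a) intersect top_N(b)| + |bottom_N(a) intersect bottom_N(b)|) /
#' (2N)`: 1 means both rankings share the same top and bottom items, 0 means
#' no overlap in either tail. Ties are broken by item id so the index is
#' deterministic.
#'
#' @param a,b Named numeric score vectors over a shared item universe.
#' @param n Number of items per tail.
#' @return Similarity in `[0, 1]`.
#' @export
top_bottom_similarity <- function(a, b, n) {
  if (is.null(names(a)) || is.null(names(b)))
    stop_validation("score vectors must be named by item id")
  shared <- intersect(names(a), names(b))
  if (2L * n > length(shared))
    stop_validation("2N (%d) exceeds the %d-item universe", 2L * n, length(shared))
  tails <- function(x) {
    x <- x[shared]
    ord <- order(-x, names(x))
    list(top = names(x)[ord[seq_len(n)]],
         bottom = names(x)[rev(ord)[seq_len(n)]])
  }
  ta <- tails(a); tb <- tails(b)
  (length(intersect(ta$top, tb$top)) + length(intersect(ta$bottom, tb$bottom))) /
    (2 * n)
}

#' Top/bottom selection sizes
#'
#' Per-resource tail sizes for the similarity index (matched to collection
#' size: pathway-like 3, hallmark-like 5, TF-like 15), plus the fraction of
#' the shared gene universe used per tail in gene space.
#'
#' @param n_by_resource Named integer vector mapping resource name to N.
#' @param gene_fraction Fraction of shared genes per tail, default 0.05.
#' @return A `top_bottom_params` list.
#' @export
top_bottom_params <- function(n_by_resource = c(pathway = 3, hallmark = 5, tf = 15),
                              gene_fraction = 0.05) {
  stopifnot(all(n_by_resource >= 1), gene_fraction > 0, gene_fraction < 0.5)
  structure(list(n_by_resource = n_by_resource, gene_fraction = gene_fraction),
            class = "top_bottom_params")
}

#' Pairwise-pipeline top/bottom similarity records
#'
#' Applies [top_bottom_similarity()] per contrast and unordered pipeline pair:
#' in set space with the resource-specific N, and in gene space with
#' `N = floor(gene_fraction * shared genes)`. Pairs whose N resolves to zero
#' are skipped with a warning.
#'
#' @param act Activity table (set space).
#' @param de DE table (gene space).
#' @param params A [top_bottom_params()] object; resources missing from
#'   `n_by_resource` raise a validation error.
#' @param spaces Subset of `c("gene", "set")`.
#' @return data.frame like [consistency_matrix()] with `metric = "similarity"`.
#' @export
similarity_matrix <- function(act = NULL, de = NULL,
                              params = top_bottom_params(),
                              spaces = c("gene", "set")) {
  spaces <- match.arg(spaces, several.ok = TRUE)
  out <- list()
  add <- function(pa, pb, contrast, space, resource, value) {
    out[[length(out) + 1L]] <<- data.frame(
      pipeline_a = pa, pipeline_b = pb, contrast = contrast, space = space,
      resource = resource, metric = "similarity", value = value,
      stringsAsFactors = FALSE)
  }
  if ("gene" %in% spaces) {
    if (is.null(de)) stop_validation("gene space requires the DE table")
    for (ct in sort(unique(de$contrast))) {
      d <- de[de$contrast == ct, ]
      pairs <- unordered_pairs(d$pipeline)
      scores <- lapply(split(d, d$pipeline), function(x)
        stats::setNames(x$stat, x$gene))
      for (k in seq_len(ncol(pairs))) {
        a <- scores[[pairs[1L, k]]]; b <- scores[[pairs[2L, k]]]
        n <- floor(params$gene_fraction * length(intersect(names(a), names(b))))
        if (n < 1L) {
          warning("gene-space N resolved to 0; pair skipped")
          next
        }
        add(pairs[1L, k], pairs[2L, k], ct, "gene", "genes",
            top_bottom_similarity(a, b, n))
      }
    }
  }
  if ("set" %in% spaces) {
    if (is.null(act)) stop_validation("set space requires the activity table")
    for (res_name in sort(unique(act$resource))) {
      if (!res_name %in% names(params$n_by_resource))
        stop_validation("no top/bottom N configured for resource '%s'", res_name)
      n <- params$n_by_resource[[res_name]]
      ar <- act[act$resource == res_name, ]
      for (ct in sort(unique(ar$contrast))) {
        d <- ar[ar$contrast == ct, ]
        pairs <- unordered_pairs(d$pipeline)
        scores <- lapply(split(d, d$pipeline), function(x)
          stats::setNames(x$score, x$set))
        for (k in seq_len(ncol(pairs)))
          add(pairs[1L, k], pairs[2L, k], ct, "set", res_name,
              top_bottom_similarity(scores[[pairs[1L, k]]],
                                    scores[[pairs[2L, k]]], n))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-sided Wilcoxon rank-sum comparison of two value groups
#'
#' Exact when the combined sample size is at most 20 and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param a,b Numeric vectors.
#' @param alternative `"greater"` (a shifted above b) or `"less"`.
#' @return list with `p`, `statistic` (rank-sum W for `a`), `exact` flag and
#'   `degenerate` flag (all values identical, `p = 1`).
#' @export
group_difference_test <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop_validation("both groups must be non-empty")
  if (length(unique(c(a, b))) == 1L)
    return(list(p = 1, statistic = length(a) * length(b) / 2,
                exact = FALSE, degenerate = TRUE))
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 20L) && !ties
  wt <- stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                           correct = TRUE)
  list(p = unname(wt$p.value), statistic = unname(wt$statistic),
       exact = exact, degenerate = FALSE)
}

#' Batch group comparisons with FDR correction
#'
#' Runs [group_difference_test()] on a list of comparisons and BH-adjusts the
#' p-values across the family.
#'
#' @param comparisons Named list; each element is a list with `a`, `b` and
#'   optionally `alternative`.
#' @return data.frame: `comparison`, `p`, `padj`.
#' @export
group_difference_table <- function(comparisons) {
  p <- vapply(comparisons, function(cmp)
    group_difference_test(cmp$a, cmp$b,
                          alternative = cmp$alternative %||% "greater")$p,
    numeric(1L))
  data.frame(comparison = names(comparisons) %||% seq_along(comparisons),
             p = unname(p), padj = stats::p.adjust(p, "BH"),
             stringsAsFactors = FALSE)
}
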