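#' Expression-filter parameters
#'
#' Parameters of the low-expression filter, matching the defaults of
#' `edgeR::filterByExpr`: a gene is kept when its CPM exceeds
#' `min_count * 1e6 / median(lib sizes)` in at least `k` samples -- where `k`
#' is the smallest group size, damped towards
#' `large_n + min_prop * (n_min - large_n)` for large groups -- and its total
#' count reaches `min_total_count`.
#'
#' @param min_count Minimum count per sample (CPM-scaled cutoff), default 10.
#' @param min_total_count Minimum total count across samples, default 15.
#' @param large_n Group size beyond which the required sample count is damped,
#'   default 10.
#' @param min_prop Proportion of samples used beyond `large_n`, default 0.7.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_count = 10, min_total_count = 15,
                          large_n = 10, min_prop = 0.7) {
  stopifnot(min_count >= 0, min_total_count >= 0, large_n >= 0,
            min_prop >= 0, min_prop <= 1)
  structure(list(min_count = min_count, min_total_count = min_total_count,
                 large_n = large_n, min_prop = min_prop),
            class = "filter_params")
}

#' Filter lowly expressed genes
#'
#' Design-aware low-expression filter: genes that are weakly expressed in all
#' groups are removed, while genes expressed in only one group survive because
#' the required number of expressing samples is tied to the smallest group
#' size. Backed by `edgeR::filterByExpr`.
#'
#' @param counts Count matrix (genes x samples).
#' @param samples Sample sheet assigning every column to a group.
#' @param params A [filter_params()] object.
#' @return Named logical vector, `TRUE` for genes to keep. Independent of
#'   sample order.
#' @export
expression_filter <- function(counts, samples, params = filter_params()) {
  assert_count_matrix(counts)
  samples <- align_samples(samples, counts)
  keep <- edgeR::filterByExpr(counts, group = factor(samples$group),
                              min.count = params$min_count,
                              min.total.count = params$min_total_count,
                              large.n = params$large_n,
                              min.prop = params$min_prop)
  names(keep) <- rownames(counts)
  if (!any(keep)) warning("expression filter removed every gene")
  keep
}

#' Signal-filter parameters for contrasts
#'
#' After differential expression, contrasts with too little signal are removed
#' before consistency analysis, so that near-null comparisons do not inject
#' noise into the functional scores. A contrast counts as having signal when
#' at least `min_de_genes` genes reach BH-adjusted p below `alpha`.
#'
#' @param alpha Adjusted-p significance threshold, default 0.05.
#' @param min_de_genes Minimum number of DE genes, default 30.
#' @param scope `"global-majority"` drops a contrast for all pipelines when it
#'   fails the threshold in the majority of pipelines (so every pipeline pair
#'   shares one contrast set); `"per-pipeline"` filters each pipeline
#'   independently.
#' @return A `signal_filter_params` list.
#' @export
signal_filter_params <- function(alpha = 0.05, min_de_genes = 30,
                                 scope = c("global-majority", "per-pipeline")) {
  stopifnot(alpha > 0, alpha < 1, min_de_genes >= 0)
  structure(list(alpha = alpha, min_de_genes = min_de_genes,
                 scope = match.arg(scope)),
            class = "signal_filter_params")
}

#' Drop contrasts without sufficient differential-expression signal
#'
#' @param de DE table as returned by [run_pipeline_grid()] (long format with
#'   `pipeline`, `contrast`, `gene`, `padj`).
#' @param params A [signal_filter_params()] object.
#' @return A list with `retained` (contrast ids kept), and `counts`, a
#'   per-(pipeline, contrast) table of DE-gene counts with a `pass` flag.
#' @export
contrast_signal_filter <- function(de, params = signal_filter_params()) {
  need <- c("pipeline", "contrast", "padj")
  if (!all(need %in% names(de)))
    stop_validation("DE table needs columns: %s", paste(need, collapse = ", "))
  if (anyNA(de$padj)) stop_validation("DE table has missing adjusted p-values")
  counts <- stats::aggregate(padj ~ pipeline + contrast, data = de,
                             FUN = function(p) sum(p < params$alpha))
  names(counts)[names(counts) == "padj"] <- "n_de_genes"
  counts$pass <- counts$n_de_genes >= params$min_de_genes
  if (params$scope == "global-majority") {
    n_pipe <- length(unique(counts$pipeline))
    fails <- tapply(!counts$pass, counts$contrast, sum)
    retained <- names(fails)[fails <= n_pipe / 2]
    counts$retained <- counts$contrast %in% retained
  } else {
    retained <- unique(counts$contrast[counts$pass])
    counts$retained <- counts$pass
  }
  list(retained = sort(retained),
       counts = counts[order(counts$pipeline, counts$contrast), ])
}
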