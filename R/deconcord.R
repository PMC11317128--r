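#' Cross-pipeline concordance analysis of one count matrix
#'
#' The main entry point: runs the requested pipeline grid on a count matrix,
#' removes contrasts without sufficient differential-expression signal,
#' enriches every pipeline's t-like statistics against the supplied gene-set
#' collections, and computes the pairwise-pipeline consistency (Spearman rank
#' correlation) and top/bottom overlap similarity, in both gene and gene-set
#' space.
#'
#' @param counts Count matrix (genes x samples) with unique gene ids, or a
#'   path readable by [read_count_matrix()].
#' @param samples Sample sheet data.frame (`sample`, `group`, covariates...).
#' @param genesets A [geneset_collection()] or list of them.
#' @param contrasts Optional contrast table; enumerated from the groups via
#'   `contrast_mode` when omitted.
#' @param pipelines Pipeline table, default the full 12-pipeline grid.
#' @param fp [filter_params()] for the expression filter.
#' @param sfp [signal_filter_params()] for the contrast signal filter.
#' @param tbp [top_bottom_params()] for the similarity index.
#' @param ulm_min_size Minimum genes per set for enrichment, default 5.
#' @param contrast_mode Passed to [enumerate_contrasts()] when `contrasts` is
#'   `NULL`.
#' @param reference Reference group for `contrast_mode = "vs-reference"`.
#' @param covariates Optional covariate column names entering the designs.
#' @return An object of class `deconcord`: a list with `de` (long DE table),
#'   `activity`, `consistency`, `similarity`, `signal_filter` (retained
#'   contrasts and per-contrast DE counts), `contrasts`, `pipelines` and the
#'   parameter objects.
#' @seealso [summary.deconcord()], [plot.deconcord()]
#' @export
deconcord <- function(counts, samples, genesets, contrasts = NULL,
                      pipelines = pipeline_grid(), fp = filter_params(),
                      sfp = signal_filter_params(), tbp = top_bottom_params(),
                      ulm_min_size = 5,
                      contrast_mode = "all-pairwise", reference = NULL,
                      covariates = NULL) {
  if (is.character(counts)) counts <- read_count_matrix(counts)
  assert_count_matrix(counts)
  samples <- align_samples(samples, counts)
  if (is.null(contrasts))
    contrasts <- enumerate_contrasts(samples, mode = contrast_mode,
                                     reference = reference)
  de <- run_pipeline_grid(counts, samples, contrasts, pipelines, fp, covariates)
  sf <- contrast_signal_filter(de, sfp)
  if (!length(sf$retained))
    stop_validation("no contrast passed the signal filter (min %d DE genes)",
                    sfp$min_de_genes)
  de_kept <- de[de$contrast %in% sf$retained, , drop = FALSE]
  activity <- enrich_all(de_kept, genesets, min_size = ulm_min_size)
  consistency <- consistency_matrix(activity, de_kept)
  similarity <- similarity_matrix(activity, de_kept, tbp)
  structure(list(de = de, activity = activity, consistency = consistency,
                 similarity = similarity, signal_filter = sf,
                 contrasts = contrasts, pipelines = pipelines,
                 params = list(filter = fp, signal = sfp, top_bottom = tbp,
                               ulm_min_size = ulm_min_size)),
            class = "deconcord")
}

#' @export
print.deconcord <- function(x, ...) {
  cat("Cross-pipeline concordance analysis\n")
  cat(sprintf("  pipelines: %d (%s)\n", nrow(x$pipelines),
              paste(utils::head(x$pipelines$id, 3L), collapse = ", ")))
  cat(sprintf("  contrasts: %d enumerated, %d retained by signal filter\n",
              nrow(x$contrasts), length(x$signal_filter$retained)))
  cat(sprintf("  DE rows: %d; activity rows: %d\n", nrow(x$de), nrow(x$activity)))
  agg <- aggregate_consistency(x$consistency)$per_pair
  for (sp in unique(agg$space))
    cat(sprintf("  mean pairwise Spearman rho (%s space): %.3f\n", sp,
                mean(agg$value[agg$space == sp], na.rm = TRUE)))
  invisible(x)
}

#' Summarise a concordance analysis
#'
#' Aggregates the pairwise records into per-pipeline mean Spearman rho and
#' mean similarity, per space and resource.
#'
#' @param object A `deconcord` object.
#' @param ... Unused.
#' @return A `summary.deconcord` list with `per_pipeline` and `per_pair`
#'   tables combining both metrics.
#' @export
summary.deconcord <- function(object, ...) {
  cons <- aggregate_consistency(object$consistency)
  sim <- aggregate_consistency(object$similarity)
  out <- list(per_pipeline = rbind(cons$per_pipeline, sim$per_pipeline),
              per_pair = rbind(cons$per_pair, sim$per_pair),
              n_retained = length(object$signal_filter$retained))
  class(out) <- "summary.deconcord"
  out
}

#' @export
print.summary.deconcord <- function(x, ...) {
  cat(sprintf("Per-pipeline concordance (over %d retained contrasts)\n",
              x$n_retained))
  tab <- x$per_pipeline
  tab$value <- round(tab$value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Heatmap of pairwise pipeline agreement
#'
#' Draws the matrix of per-pair mean values (Spearman rho by default) for one
#' space/resource as a base-graphics image.
#'
#' @param x A `deconcord` object.
#' @param metric `"spearman"` or `"similarity"`.
#' @param space `"set"` or `"gene"`.
#' @param resource Resource name (default: first available in that space).
#' @param ... Passed to [graphics::image()].
#' @return The plotted matrix, invisibly.
#' @export
plot.deconcord <- function(x, metric = c("spearman", "similarity"),
                           space = c("set", "gene"), resource = NULL, ...) {
  metric <- match.arg(metric)
  space <- match.arg(space)
  rec <- if (metric == "spearman") x$consistency else x$similarity
  rec <- rec[rec$space == space, ]
  resource <- resource %||% rec$resource[1L]
  rec <- rec[rec$resource == resource, ]
  agg <- stats::aggregate(value ~ pipeline_a + pipeline_b, data = rec,
                          FUN = mean, na.rm = TRUE)
  ids <- sort(unique(c(agg$pipeline_a, agg$pipeline_b)))
  m <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(agg$pipeline_a, agg$pipeline_b)] <- agg$value
  m[cbind(agg$pipeline_b, agg$pipeline_a)] <- agg$value
  op <- graphics::par(mar = c(9, 9, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_along(ids), seq_along(ids), m, axes = FALSE,
                  xlab = "", ylab = "",
                  main = sprintf("%s (%s space, %s)", metric, space, resource),
                  ...)
  graphics::axis(1, seq_along(ids), ids, las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_along(ids), ids, las = 2, cex.axis = 0.7)
  invisible(m)
}
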