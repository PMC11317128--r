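#' Univariate-linear-model gene-set enrichment
#'
#' For each gene set, the per-gene t-like statistics are regressed on the
#' set's membership-weight vector over the full gene universe (weight for
#' member genes, 0 elsewhere) with an intercept; the activity score is the
#' t-value of the regression slope, which carries the direction of the
#' enrichment in its sign and its significance in its magnitude. Sets with
#' fewer than `min_size` genes present in the statistics vector are skipped.
#'
#' @param stats Named numeric vector of t-like statistics indexed by gene id;
#'   more than two genes required.
#' @param coll A [geneset_collection()].
#' @param min_size Minimum number of member genes present, default 5.
#' @return data.frame with `set`, `score` (slope t-value), `p` (two-sided,
#'   `length(stats) - 2` df) and `n_genes` (members present). A set whose
#'   weight vector has zero variance gets `score = 0`, `p = 1`.
#' @examples
#' stats <- c(g1 = 1, g2 = 2, g3 = 3, g4 = 4)
#' coll <- geneset_collection(data.frame(set = "s", gene = c("g3", "g4")))
#' ulm_enrich(stats, coll, min_size = 2)
#' @export
ulm_enrich <- function(stats, coll, min_size = 5) {
  if (is.null(names(stats)) || length(stats) <= 2L)
    stop_validation("stats must be a named vector over more than two genes")
  genes <- names(stats)
  n <- length(stats)
  in_universe <- coll$gene %in% genes
  cc <- coll[in_universe, , drop = FALSE]
  sizes <- table(cc$set)
  keep_sets <- names(sizes)[sizes >= min_size]
  if (!length(keep_sets))
    return(data.frame(set = character(), score = numeric(), p = numeric(),
                      n_genes = integer(), stringsAsFactors = FALSE))
  cc <- cc[cc$set %in% keep_sets, , drop = FALSE]
  # membership-weight matrix, genes x sets, zeros for non-members
  X <- matrix(0, nrow = n, ncol = length(keep_sets),
              dimnames = list(genes, sort(keep_sets)))
  X[cbind(match(cc$gene, genes), match(cc$set, colnames(X)))] <- cc$weight
  y <- as.numeric(stats)
  df <- n - 2L
  sx <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sx > 0 & stats::sd(y) > 0
  if (any(ok)) r[ok] <- as.numeric(stats::cor(X[, ok, drop = FALSE], y))
  r <- pmin(pmax(r, -1), 1)
  tt <- ifelse(abs(r) >= 1, sign(r) * Inf, r * sqrt(df / (1 - r^2)))
  p <- 2 * stats::pt(abs(tt), df = df, lower.tail = FALSE)
  tt[!ok] <- 0
  p[!ok] <- 1
  data.frame(set = colnames(X), score = tt, p = p,
             n_genes = as.integer(sizes[colnames(X)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Enrich every pipeline and contrast against gene-set collections
#'
#' Applies [ulm_enrich()] to the t-like statistic column of a DE table for
#' each (pipeline, contrast, resource). The gene universe is whatever genes
#' the pipeline reports, so filtered and unfiltered pipelines use different
#' universes -- exactly the downstream effect the consistency modules
#' quantify.
#'
#' @param de Long DE table from [run_pipeline_grid()].
#' @param collections A single [geneset_collection()] or a list of them.
#' @param min_size Minimum member genes per set, default 5.
#' @return Activity table: `pipeline`, `contrast`, `resource`, `set`,
#'   `score`, `p`.
#' @export
enrich_all <- function(de, collections, min_size = 5) {
  if (inherits(collections, "geneset_collection"))
    collections <- list(collections)
  names(collections) <- vapply(collections, function(x)
    attr(x, "name") %||% "collection", character(1L))
  need <- c("pipeline", "contrast", "gene", "stat")
  if (!all(need %in% names(de)))
    stop_validation("DE table needs columns: %s", paste(need, collapse = ", "))
  chunks <- split(de, list(de$pipeline, de$contrast), drop = TRUE)
  out <- list()
  for (chunk in chunks) {
    stats_vec <- stats::setNames(chunk$stat, chunk$gene)
    for (res_name in names(collections)) {
      coll <- collections[[res_name]]
      if (!any(coll$gene %in% names(stats_vec))) {
        warning(sprintf("resource '%s' shares no genes with pipeline %s; skipped",
                        res_name, chunk$pipeline[1L]))
        next
      }
      rows <- ulm_enrich(stats_vec, coll, min_size = min_size)
      if (!nrow(rows)) next
      rows$pipeline <- chunk$pipeline[1L]
      rows$contrast <- chunk$contrast[1L]
      rows$resource <- res_name
      out[[length(out) + 1L]] <-
        rows[, c("pipeline", "contrast", "resource", "set", "score", "p")]
    }
  }
  if (!length(out))
    return(data.frame(pipeline = character(), contrast = character(),
                      resource = character(), set = character(),
                      score = numeric(), p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
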