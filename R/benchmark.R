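#' Pseudobulk aggregation of single-cell counts
#'
#' Sums UMI counts of all cells belonging to each (sample, cell type) pair
#' into one pseudobulk profile, then removes pseudobulks built from fewer than
#' `min_cells` cells or with a total count below `min_counts`. Cells without a
#' cell-type label are discarded.
#'
#' @param cell_counts Gene x cell count matrix.
#' @param cell_meta data.frame with columns `cell`, `sample`, `cell_type`
#'   (NA cell types are dropped).
#' @param min_cells Minimum cells per pseudobulk, default 10.
#' @param min_counts Minimum total counts per pseudobulk, default 1000.
#' @return list with `counts` (gene x pseudobulk matrix), `samples` (sample
#'   sheet: `sample` = pseudobulk id, `group` = cell type, `origin` = source
#'   sample, `n_cells`), and `dropped` (ids of filtered-out pseudobulks).
#' @export
pseudobulk <- function(cell_counts, cell_meta, min_cells = 10, min_counts = 1000) {
  if (!all(c("cell", "sample", "cell_type") %in% names(cell_meta)))
    stop_validation("cell metadata needs 'cell', 'sample', 'cell_type' columns")
  if (!all(colnames(cell_counts) %in% cell_meta$cell))
    stop_validation("cells missing from metadata")
  meta <- cell_meta[match(colnames(cell_counts), cell_meta$cell), ]
  keep <- !is.na(meta$cell_type)
  counts <- cell_counts[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  pb_id <- paste(meta$sample, meta$cell_type, sep = "|")
  agg <- t(rowsum(t(counts), group = pb_id, reorder = TRUE))
  n_cells <- as.integer(table(pb_id)[colnames(agg)])
  totals <- colSums(agg)
  ok <- n_cells >= min_cells & totals >= min_counts
  if (!any(ok)) stop_validation("no pseudobulk passed the quality filters")
  dropped <- colnames(agg)[!ok]
  agg <- agg[, ok, drop = FALSE]
  info <- data.frame(
    sample = colnames(agg),
    group = sub("^[^|]*\\|", "", colnames(agg)),
    origin = sub("\\|.*$", "", colnames(agg)),
    n_cells = n_cells[ok], stringsAsFactors = FALSE)
  storage.mode(agg) <- "integer"
  list(counts = agg, samples = info, dropped = dropped)
}

#' Cell-type marker ground truth
#'
#' For one-vs-rest contrasts over cell types, every marker set is a candidate
#' for every contrast; the set named after the contrast's target cell type is
#' the single true positive.
#'
#' @param contrasts Contrast table (numerators are cell types).
#' @param marker_sets [geneset_collection()] with one set per cell type, set
#'   ids equal to the cell-type labels.
#' @return Truth table: `contrast`, `candidate`, `label` (0/1).
#' @export
build_marker_truth <- function(contrasts, marker_sets) {
  candidates <- sort(unique(marker_sets$set))
  unmapped <- setdiff(unique(contrasts$numerator), candidates)
  if (length(unmapped))
    stop_validation("cell types without marker sets: %s",
                    paste(unmapped, collapse = ", "))
  out <- expand.grid(contrast = contrasts$id, candidate = candidates,
                     stringsAsFactors = FALSE)
  target <- contrasts$numerator[match(out$contrast, contrasts$id)]
  out$label <- as.integer(out$candidate == target)
  out[order(out$contrast, out$candidate), ]
}

#' Assign transcription factors to cell types by binding affinity
#'
#' TFs absent from the regulon collection are discarded, then (cell type, TF)
#' rows are visited in descending binding score (ties broken by TF id) and
#' each TF is granted to the first cell type that claims it, until a cell
#' type holds `k` TFs. A TF therefore belongs to at most one cell type, and
#' cell types whose candidates were claimed elsewhere end with fewer than `k`
#' markers.
#'
#' @param binding data.frame with columns `cell_type`, `tf`, `score`.
#' @param k Maximum TFs per cell type, default 10.
#' @param coll TF regulon [geneset_collection()] (set ids are TFs).
#' @return data.frame `cell_type`, `tf`, `score`, sorted by cell type then
#'   descending score.
#' @export
assign_tf_markers <- function(binding, k = 10, coll) {
  if (!all(c("cell_type", "tf", "score") %in% names(binding)))
    stop_validation("binding table needs 'cell_type', 'tf', 'score' columns")
  binding <- binding[binding$tf %in% unique(coll$set), , drop = FALSE]
  if (!nrow(binding)) stop_validation("no binding rows left after regulon filter")
  binding <- binding[order(-binding$score, binding$tf, binding$cell_type), ]
  taken <- character()
  held <- stats::setNames(integer(length(unique(binding$cell_type))),
                          unique(binding$cell_type))
  rows <- logical(nrow(binding))
  for (i in seq_len(nrow(binding))) {
    ct <- binding$cell_type[i]; tf <- binding$tf[i]
    if (tf %in% taken || held[[ct]] >= k) next
    taken <- c(taken, tf)
    held[[ct]] <- held[[ct]] + 1L
    rows[i] <- TRUE
  }
  out <- binding[rows, c("cell_type", "tf", "score")]
  out <- out[order(out$cell_type, -out$score, out$tf), ]
  rownames(out) <- NULL
  out
}

#' Perturbation-to-gene-set ground truth
#'
#' Each contrast corresponds to a perturbation; its mapped gene set(s) are the
#' true positives and all other mapped sets are negatives. Contrasts whose
#' perturbation is absent from the mapping are excluded with a message.
#'
#' @param contrasts data.frame with columns `id` and `perturbation`.
#' @param mapping data.frame with columns `perturbation`, `gene_set`.
#' @return Truth table: `contrast`, `candidate`, `label`.
#' @export
perturbation_truth <- function(contrasts, mapping) {
  if (!all(c("perturbation", "gene_set") %in% names(mapping)))
    stop_validation("mapping needs 'perturbation' and 'gene_set' columns")
  candidates <- sort(unique(mapping$gene_set))
  mapped <- contrasts$perturbation %in% mapping$perturbation
  if (!any(mapped)) stop_validation("no contrast has a mapped perturbation")
  if (any(!mapped))
    message(sprintf("excluding %d contrasts with unmapped perturbations",
                    sum(!mapped)))
  cts <- contrasts[mapped, , drop = FALSE]
  out <- expand.grid(contrast = cts$id, candidate = candidates,
                     stringsAsFactors = FALSE)
  pert <- cts$perturbation[match(out$contrast, cts$id)]
  key <- paste(pert, out$candidate)
  truth_key <- paste(mapping$perturbation, mapping$gene_set)
  out$label <- as.integer(key %in% truth_key)
  out[order(out$contrast, out$candidate), ]
}

#' Pool enrichment scores across contrasts and rank them
#'
#' Joins a truth table with the activity scores and, per pipeline (and
#' optional scope grouping), concatenates all (contrast, candidate) instances
#' and orders them by descending score, ties broken by contrast then
#' candidate id.
#'
#' @param act Activity table restricted to the benchmark resource.
#' @param truth Truth table (`contrast`, `candidate`, `label`).
#' @param scope Optional named character vector mapping contrast id to a scope
#'   label (e.g. study); `NULL` pools everything.
#' @return data.frame `pipeline`, `scope`, `contrast`, `candidate`, `score`,
#'   `label`, ranked within (pipeline, scope).
#' @export
pooled_rank <- function(act, truth, scope = NULL) {
  key_truth <- paste(truth$contrast, truth$candidate)
  out <- list()
  for (pl in sort(unique(act$pipeline))) {
    a <- act[act$pipeline == pl, ]
    key_act <- paste(a$contrast, a$set)
    idx <- match(key_truth, key_act)
    if (anyNA(idx))
      stop_validation("missing scores for pipeline %s: %s", pl,
                      paste(utils::head(key_truth[is.na(idx)], 5L), collapse = "; "))
    d <- data.frame(pipeline = pl,
                    scope = if (is.null(scope)) "all" else
                      unname(scope[truth$contrast]),
                    contrast = truth$contrast, candidate = truth$candidate,
                    score = a$score[idx], label = truth$label,
                    stringsAsFactors = FALSE)
    d <- d[order(d$scope, -d$score, d$contrast, d$candidate), ]
    out[[pl]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

check_labels <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_validation("labels and scores differ in length")
  if (!all(labels %in% c(0, 1))) stop_validation("labels must be 0/1")
  if (all(labels == 1) || all(labels == 0))
    stop_validation("need at least one positive and one negative")
}

#' Area under the ROC curve
#'
#' Tie-aware probability that a random positive outscores a random negative
#' (ties count one half); equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, larger = more confident positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  check_labels(labels, scores)
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Average-precision formulation: sweeping thresholds over distinct score
#' values in descending order, the area is the sum of precision times the
#' recall increment at each threshold. Tied score blocks are processed
#' atomically, avoiding the optimistic bias of trapezoidal interpolation on
#' PR curves.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  check_labels(labels, scores)
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  # last index of each tied block along the descending sweep
  ends <- which(c(diff(s) != 0, TRUE))
  tp <- cumsum(l)[ends]
  precision <- tp / ends
  recall <- tp / sum(l)
  sum(precision * diff(c(0, recall)))
}

#' Score pipelines against a ground truth
#'
#' Pools scores with [pooled_rank()] and reports tie-aware AUROC and AUPRC per
#' (pipeline, scope).
#'
#' @inheritParams pooled_rank
#' @param benchmark_id Label for the report.
#' @return data.frame: `pipeline`, `benchmark`, `scope`, `auroc`, `auprc`,
#'   `n_pos`, `n_neg`.
#' @export
benchmark_score <- function(act, truth, scope = NULL, benchmark_id = "benchmark") {
  ranked <- pooled_rank(act, truth, scope)
  chunks <- split(ranked, list(ranked$pipeline, ranked$scope), drop = TRUE)
  rows <- lapply(chunks, function(d) data.frame(
    pipeline = d$pipeline[1L], benchmark = benchmark_id, scope = d$scope[1L],
    auroc = auroc(d$label, d$score), auprc = auprc(d$label, d$score),
    n_pos = sum(d$label == 1), n_neg = sum(d$label == 0),
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$pipeline, out$scope), ]
  rownames(out) <- NULL
  out
}
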