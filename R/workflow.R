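#' Run configuration
#'
#' Flat, serializable configuration for [run_workflow()]. Defaults mirror the
#' documented method defaults: expression-filter cutoffs 10/15, a minimum of
#' 30 DE genes per retained contrast, 5 genes per enriched set, top/bottom
#' N of 3/5/15 for pathway/hallmark/TF-like resources and 5% per tail for
#' genes.
#'
#' @param counts Path to the count TSV.
#' @param metadata Path to the sample sheet TSV.
#' @param genesets Named character vector of gene-set files (`name = path`).
#' @param contrasts Optional path to a contrast TSV (`numerator`,
#'   `denominator`).
#' @param outdir Output directory.
#' @param pipelines Pipeline ids to run, default the full grid.
#' @param contrast_mode Contrast enumeration mode.
#' @param reference Reference group for `vs-reference`.
#' @param min_count,min_total_count Expression-filter cutoffs.
#' @param alpha,min_de_genes Signal-filter parameters.
#' @param ulm_min_size Minimum genes per set.
#' @param top_n Named numeric vector resource -> N for the similarity index.
#' @param gene_top_frac Per-tail gene fraction.
#' @param seed Integer seed recorded in the log.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, metadata, genesets, contrasts = NULL,
                       outdir = "deconcord_out",
                       pipelines = pipeline_grid()$id,
                       contrast_mode = "all-pairwise", reference = NULL,
                       min_count = 10, min_total_count = 15,
                       alpha = 0.05, min_de_genes = 30, ulm_min_size = 5,
                       top_n = c(pathway = 3, hallmark = 5, tf = 15),
                       gene_top_frac = 0.05, seed = 1L) {
  structure(list(counts = counts, metadata = metadata,
                 genesets = as.list(genesets), contrasts = contrasts,
                 outdir = outdir, pipelines = pipelines,
                 contrast_mode = contrast_mode, reference = reference,
                 min_count = min_count, min_total_count = min_total_count,
                 alpha = alpha, min_de_genes = min_de_genes,
                 ulm_min_size = ulm_min_size, top_n = as.list(top_n),
                 gene_top_frac = gene_top_frac, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration (YAML)
#'
#' @param config A [run_config()] object.
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the `run_config`. Round-trips exactly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, c(
    raw[c("counts", "metadata")],
    list(genesets = unlist(raw$genesets), contrasts = raw$contrasts,
         outdir = raw$outdir, pipelines = unlist(raw$pipelines),
         contrast_mode = raw$contrast_mode, reference = raw$reference,
         min_count = raw$min_count, min_total_count = raw$min_total_count,
         alpha = raw$alpha, min_de_genes = raw$min_de_genes,
         ulm_min_size = raw$ulm_min_size, top_n = unlist(raw$top_n),
         gene_top_frac = raw$gene_top_frac, seed = raw$seed)))
}

#' Execute a configured workflow and write the four result files
#'
#' Reads the inputs, runs [deconcord()], and writes to `outdir`:
#' `de_results.tsv` (merged long DE table, plus one TSV per pipeline x
#' contrast under `de/`), `activity_scores.tsv`, `rank_correlation.tsv` and
#' `similarity.tsv`, together with the signal-filter report, aggregated
#' summaries, the serialized configuration and a run log (package version,
#' seed, config checksum).
#'
#' @param config A [run_config()] object or path to its YAML file.
#' @return The `deconcord` object, invisibly; outputs on disk.
#' @export
run_workflow <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  counts <- read_count_matrix(config$counts)
  if (attr(counts, "duplicated_gene_ids") %||% FALSE)
    counts <- aggregate_gene_ids(counts)
  samples <- read_sample_sheet(config$metadata)
  colls <- lapply(names(config$genesets), function(nm)
    read_gene_sets(config$genesets[[nm]], name = nm))
  contrasts <- NULL
  if (!is.null(config$contrasts)) {
    user <- utils::read.table(config$contrasts, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    contrasts <- enumerate_contrasts(samples, user_list = user)
  }
  grid <- pipeline_grid()
  grid <- grid[grid$id %in% config$pipelines, , drop = FALSE]
  if (!nrow(grid)) stop_validation("no known pipeline id in configuration")
  res <- deconcord(
    counts, samples, colls, contrasts = contrasts, pipelines = grid,
    fp = filter_params(min_count = config$min_count,
                       min_total_count = config$min_total_count),
    sfp = signal_filter_params(alpha = config$alpha,
                               min_de_genes = config$min_de_genes),
    tbp = top_bottom_params(n_by_resource = unlist(config$top_n),
                            gene_fraction = config$gene_top_frac),
    ulm_min_size = config$ulm_min_size,
    contrast_mode = config$contrast_mode, reference = config$reference)

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  wt <- function(x, path) utils::write.table(x, path, sep = "\t", quote = FALSE,
                                             row.names = FALSE)
  wt(res$de, out("de_results.tsv"))
  dir.create(out("de"), showWarnings = FALSE)
  for (chunk in split(res$de, list(res$de$pipeline, res$de$contrast), drop = TRUE))
    wt(chunk, out("de", sprintf("%s__%s.tsv", chunk$pipeline[1L],
                                gsub("[^A-Za-z0-9_.-]", "_", chunk$contrast[1L]))))
  wt(res$activity, out("activity_scores.tsv"))
  wt(res$consistency, out("rank_correlation.tsv"))
  wt(res$similarity, out("similarity.tsv"))
  wt(res$signal_filter$counts, out("signal_filter.tsv"))
  agg <- summary(res)
  wt(agg$per_pair, out("summary_per_pair.tsv"))
  wt(agg$per_pipeline, out("summary_per_pipeline.tsv"))
  cfg_path <- out("config.yaml")
  write_run_config(config, cfg_path)
  writeLines(c(
    sprintf("deconcord %s", as.character(utils::packageVersion("deconcord"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", config$seed),
    sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
    sprintf("finished: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
    out("run_log.txt"))
  invisible(res)
}
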