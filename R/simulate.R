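# Synthetic-data generators: negative-binomial bulk counts with group
# structure, library-size variation and a low-count gene stratum; single-cell
# counts with cell-type markers for the pseudobulk benchmark; and toy gene-set
# collections shaped like the three prior-knowledge resources the enrichment
# stage consumes (14 pathway footprints, 50 hallmarks, signed TF regulons).

#' Deterministic gene identifiers
#'
#' Shared gene universe naming used by the simulators and toy collections.
#'
#' @param n Number of genes.
#' @return Character vector `g0001`, `g0002`, ...
#' @export
gene_ids <- function(n) sprintf("g%04d", seq_len(n))

rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, lambda = mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate bulk RNA-seq counts with planted effects
#'
#' Counts are negative binomial with variance `mu + dispersion * mu^2`. The
#' per-gene baseline mean is log-normally spread around `baseline_mu` (one
#' doubling of spread) to emulate the dynamic range of expression, except for
#' a `low_count_fraction` stratum whose baselines are drawn near 1 -- the
#' lowly expressed genes the expression filter targets. Low-count genes are
#' additionally contaminated by sporadic expression bursts (an observation
#' jumps to a mean of `low_burst_mu` with probability `low_burst_prob`,
#' independent of group), emulating the dropout-and-burst behaviour of
#' near-zero genes in sequencing data that makes their statistics unreliable;
#' set `low_burst_prob = 0` for a clean negative-binomial stratum. Per-sample
#' library factors are log-normal with coefficient of variation `libsize_cv`.
#' Group effects multiply the mean by `2^lfc` for the genes and groups named
#' in `lfc_map`. Everything is deterministic given `seed`.
#'
#' @param n_genes Number of genes.
#' @param groups Named integer vector: samples per group, e.g. `c(A = 5, B = 5)`.
#' @param baseline_mu Median baseline mean count, default 150.
#' @param dispersion NB dispersion (0 gives the Poisson limit), default 0.2.
#' @param lfc_map Planted log2 fold changes: either a named list
#'   `group -> named gene lfc vector`, or a single named gene vector applied
#'   to the last group.
#' @param libsize_cv Coefficient of variation of library factors, default 0.2.
#' @param low_count_fraction Fraction of genes in the near-zero stratum,
#'   default 0.3.
#' @param low_genes Optional explicit gene ids for the low-count stratum
#'   (overrides the random draw controlled by `low_count_fraction`).
#' @param low_burst_prob Per-observation probability of a sporadic burst in a
#'   low-count gene, default 0.08.
#' @param low_burst_mu Mean count of a burst observation, default 30.
#' @param seed Integer seed.
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (sample sheet) and `truth` (planted lfc map, low-count gene ids,
#'   parameters, seed).
#' @export
simulate_bulk_counts <- function(n_genes, groups = c(A = 5, B = 5),
                                 baseline_mu = 150, dispersion = 0.2,
                                 lfc_map = NULL, libsize_cv = 0.2,
                                 low_count_fraction = 0.3, low_genes = NULL,
                                 low_burst_prob = 0.08, low_burst_mu = 30,
                                 seed = 1L) {
  if (n_genes < 2L || any(groups < 1L) || baseline_mu <= 0 || dispersion < 0 ||
      libsize_cv < 0 || low_count_fraction < 0 || low_count_fraction >= 1)
    stop_validation("invalid simulation parameters")
  set.seed(seed)
  genes <- gene_ids(n_genes)
  group_names <- names(groups)
  if (is.null(group_names)) stop_validation("groups must be a named vector")
  if (!is.null(lfc_map) && !is.list(lfc_map))
    lfc_map <- stats::setNames(list(lfc_map), group_names[length(group_names)])

  base <- baseline_mu * 2^stats::rnorm(n_genes)
  if (is.null(low_genes)) {
    n_low <- round(low_count_fraction * n_genes)
    low_idx <- sample(n_genes, n_low)
  } else {
    low_idx <- match(intersect(low_genes, genes), genes)
    n_low <- length(low_idx)
  }
  base[low_idx] <- stats::runif(n_low, 0.5, 2)

  sample_group <- rep(group_names, times = groups)
  n_samples <- length(sample_group)
  sample_id <- sprintf("s%03d", seq_len(n_samples))
  lib <- rlnorm_cv(n_samples, libsize_cv)

  lfc <- matrix(0, n_genes, length(group_names),
                dimnames = list(genes, group_names))
  for (g in names(lfc_map %||% list())) {
    v <- lfc_map[[g]]
    hit <- intersect(names(v), genes)
    lfc[hit, g] <- v[hit]
  }
  mu <- outer(base, lib) * 2^lfc[, sample_group, drop = FALSE]
  if (n_low > 0L && low_burst_prob > 0) {
    burst <- matrix(stats::runif(n_low * n_samples) < low_burst_prob,
                    nrow = n_low)
    mu[low_idx, ][burst] <- low_burst_mu
  }
  counts <- matrix(rnb(length(mu), mu = as.vector(mu), dispersion = dispersion),
                   nrow = n_genes, dimnames = list(genes, sample_id))
  storage.mode(counts) <- "integer"
  samples <- data.frame(sample = sample_id, group = sample_group,
                        stringsAsFactors = FALSE)
  truth <- list(lfc_map = lfc_map, low_genes = genes[low_idx],
                groups = groups, dispersion = dispersion,
                low_count_fraction = low_count_fraction,
                libsize_cv = libsize_cv, baseline_mu = baseline_mu, seed = seed)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate single-cell counts with cell-type markers
#'
#' Each cell type over-expresses its own marker genes by a known fold over a
#' low background mean; the matching marker collection is returned so the
#' pseudobulk benchmark can close the loop from simulated cells to ground
#' truth.
#'
#' @param cell_types Character vector of at least two cell-type labels.
#' @param markers_per_type Marker genes per type, default 15.
#' @param cells_per_sample Cells per (sample, cell type): scalar or named
#'   vector by cell type.
#' @param samples Number of samples (replicates), default 4.
#' @param n_background Background (non-marker) genes, default 300.
#' @param background_mu Per-cell background mean, default 0.2.
#' @param marker_fold Fold over-expression of markers in their own type,
#'   default 8.
#' @param dispersion NB dispersion at cell level, default 0.5.
#' @param seed Integer seed.
#' @return list with `counts` (gene x cell), `meta` (`cell`, `sample`,
#'   `cell_type`) and `markers` (a [geneset_collection()], one set per type).
#' @export
simulate_cell_counts <- function(cell_types, markers_per_type = 15,
                                 cells_per_sample = 30, samples = 4,
                                 n_background = 300, background_mu = 0.2,
                                 marker_fold = 8, dispersion = 0.5, seed = 1L) {
  if (length(cell_types) < 2L) stop_validation("need at least two cell types")
  set.seed(seed)
  k <- length(cell_types)
  n_genes <- k * markers_per_type + n_background
  genes <- gene_ids(n_genes)
  marker_sets <- stats::setNames(
    split(genes[seq_len(k * markers_per_type)],
          rep(seq_len(k), each = markers_per_type)), cell_types)
  if (is.null(names(cells_per_sample)))
    cells_per_sample <- stats::setNames(rep(cells_per_sample[1L], k), cell_types)
  meta <- do.call(rbind, lapply(seq_len(samples), function(s) {
    do.call(rbind, lapply(cell_types, function(ct)
      data.frame(sample = sprintf("smp%02d", s), cell_type = ct,
                 n = cells_per_sample[[ct]], stringsAsFactors = FALSE)))
  }))
  meta <- meta[rep(seq_len(nrow(meta)), meta$n), c("sample", "cell_type")]
  meta$cell <- sprintf("cell%05d", seq_len(nrow(meta)))
  rownames(meta) <- NULL

  mu_mat <- matrix(background_mu, nrow = n_genes, ncol = k,
                   dimnames = list(genes, cell_types))
  for (ct in cell_types)
    mu_mat[marker_sets[[ct]], ct] <- background_mu * marker_fold
  mu <- mu_mat[, meta$cell_type, drop = FALSE]
  counts <- matrix(rnb(length(mu), as.vector(mu), dispersion),
                   nrow = n_genes, dimnames = list(genes, meta$cell))
  storage.mode(counts) <- "integer"
  markers <- geneset_collection(
    data.frame(set = rep(cell_types, each = markers_per_type),
               gene = unlist(marker_sets, use.names = FALSE), weight = 1),
    name = "markers")
  list(counts = counts, meta = meta[, c("cell", "sample", "cell_type")],
       markers = markers)
}

#' Toy gene-set collections shaped like the three standard resources
#'
#' Builds, over a shared synthetic gene universe: a pathway-like collection
#' (14 sets with continuous signed footprint weights), a hallmark-like
#' collection (50 membership sets, weight 1) and a TF-like collection of
#' signed regulons (+1 activation, -1 repression). Every set has at least 5
#' genes, the enrichment default minimum.
#'
#' @param seed Integer seed.
#' @param n_genes Size of the gene universe, default 1000.
#' @return Named list of three [geneset_collection()] objects: `pathway`,
#'   `hallmark`, `tf`.
#' @export
make_toy_collections <- function(seed = 1L, n_genes = 1000) {
  set.seed(seed)
  genes <- gene_ids(n_genes)
  draw <- function(prefix, n_sets, size_range, weight_fun) {
    do.call(rbind, lapply(seq_len(n_sets), function(i) {
      size <- sample(size_range, 1L)
      data.frame(set = sprintf("%s%02d", prefix, i),
                 gene = sample(genes, size), weight = weight_fun(size),
                 stringsAsFactors = FALSE)
    }))
  }
  pathway <- draw("PW", 14L, 30:60, function(n) stats::rnorm(n))
  hallmark <- draw("HM", 50L, 12:20, function(n) rep(1, n))
  tf <- draw("TF", 30L, 8:25, function(n)
    sample(c(1, -1), n, replace = TRUE, prob = c(0.8, 0.2)))
  list(pathway = geneset_collection(pathway, name = "pathway"),
       hallmark = geneset_collection(hallmark, name = "hallmark"),
       tf = geneset_collection(tf, name = "tf"))
}

#' Low-signal concordance scenario
#'
#' Several multi-group bulk datasets with weak planted gene-set effects
#' (default log2 fold change 0.5) and a heavy low-count stratum (40% of
#' genes), the regime in which gene filtering is expected to matter most for
#' downstream enrichment concordance. Each group perturbs a few hallmark-like
#' sets in a random direction; all-pairwise contrasts are enumerated per
#' dataset.
#'
#' @param seed Integer seed.
#' @param n_datasets Number of independent datasets, default 2.
#' @param n_groups Groups per dataset, default 6 (so 15 pairwise contrasts
#'   each).
#' @param n_per_group Samples per group, default 4.
#' @param n_genes Genes, default 800.
#' @param lfc Planted log2 fold change, default 0.5.
#' @param low_count_fraction Fraction of near-zero genes, default 0.4.
#' @param sets_per_group Hallmark sets perturbed per group, default 3.
#' @return list with `datasets` (each: `counts`, `samples`, `contrasts`,
#'   `truth`) and `collections`.
#' @export
scenario_low_signal <- function(seed = 1L, n_datasets = 2, n_groups = 6,
                                n_per_group = 4, n_genes = 800, lfc = 0.5,
                                low_count_fraction = 0.4, sets_per_group = 3) {
  coll <- make_toy_collections(seed, n_genes = n_genes)
  hm <- coll$hallmark
  datasets <- lapply(seq_len(n_datasets), function(d) {
    set.seed(seed + 1000L * d)
    group_names <- paste0("grp", LETTERS[seq_len(n_groups)])
    # the near-zero stratum carries technical noise only: planted effects are
    # restricted to adequately expressed genes
    low_genes <- sample(gene_ids(n_genes), round(low_count_fraction * n_genes))
    lfc_map <- lapply(stats::setNames(group_names, group_names), function(g) {
      sets <- sample(unique(hm$set), sets_per_group)
      genes <- setdiff(unique(hm$gene[hm$set %in% sets]), low_genes)
      stats::setNames(sample(c(lfc, -lfc), length(genes), replace = TRUE), genes)
    })
    sim <- simulate_bulk_counts(
      n_genes, groups = stats::setNames(rep(n_per_group, n_groups), group_names),
      dispersion = 0.3, lfc_map = lfc_map, low_genes = low_genes,
      seed = seed + 1000L * d + 1L)
    sim$samples$sample <- paste0("d", d, "_", sim$samples$sample)
    colnames(sim$counts) <- sim$samples$sample
    contrasts <- enumerate_contrasts(sim$samples)
    contrasts$id <- paste0("ds", d, ":", contrasts$id)
    c(sim, list(contrasts = contrasts))
  })
  list(datasets = datasets, collections = coll)
}

#' Perturbation-response benchmark scenario
#'
#' A control group plus a panel of perturbation groups; a fraction of the
#' perturbations (default 60%) genuinely shift the genes of their mapped
#' hallmark set, the rest are null, emulating a moderate-signal benchmark in
#' which only responsive contrasts carry their planted signature. A heavy
#' low-count stratum stresses the filtering arm. The perturbation-to-hallmark
#' map covers 6 candidate sets, giving a 1-in-6 baseline prevalence.
#'
#' @param seed Integer seed.
#' @param n_perturbations Number of perturbation groups, default 10.
#' @param responsive_fraction Fraction with a real planted signal, default 0.6.
#' @param n_per_group Samples per group, default 4.
#' @param n_genes Genes, default 800.
#' @param lfc Planted log2 fold change for responsive perturbations, default 1.5.
#' @param low_count_fraction Fraction of near-zero genes, default 0.5.
#' @return list with `counts`, `samples`, `contrasts` (vs control, with a
#'   `perturbation` column), `mapping` (perturbation to hallmark), `truth`
#'   table, and `collections`.
#' @export
scenario_benchmark3 <- function(seed = 1L, n_perturbations = 10,
                                responsive_fraction = 0.6, n_per_group = 4,
                                n_genes = 800, lfc = 1.5,
                                low_count_fraction = 0.5) {
  coll <- make_toy_collections(seed, n_genes = n_genes)
  hm <- coll$hallmark
  set.seed(seed + 7L)
  candidates <- sample(unique(hm$set), 6L)
  perts <- sprintf("pert%02d", seq_len(n_perturbations))
  mapping <- data.frame(perturbation = perts,
                        gene_set = rep_len(candidates, n_perturbations),
                        stringsAsFactors = FALSE)
  # noise-only near-zero stratum; responses live in expressed genes
  low_genes <- sample(gene_ids(n_genes), round(low_count_fraction * n_genes))
  responsive <- seq_len(round(responsive_fraction * n_perturbations))
  lfc_map <- list()
  for (i in responsive) {
    genes <- setdiff(unique(hm$gene[hm$set == mapping$gene_set[i]]), low_genes)
    lfc_map[[perts[i]]] <- stats::setNames(rep(lfc, length(genes)), genes)
  }
  sizes <- stats::setNames(rep(n_per_group, n_perturbations + 1L),
                           c("control", perts))
  sim <- simulate_bulk_counts(n_genes, groups = sizes, dispersion = 0.3,
                              lfc_map = lfc_map, low_genes = low_genes,
                              seed = seed)
  contrasts <- enumerate_contrasts(sim$samples, mode = "vs-reference",
                                   reference = "control")
  contrasts$perturbation <- contrasts$numerator
  truth <- perturbation_truth(contrasts, mapping)
  list(counts = sim$counts, samples = sim$samples, contrasts = contrasts,
       mapping = mapping, truth = truth, collections = coll,
       responsive = perts[responsive], sim_truth = sim$truth)
}

#' Pseudobulk cell-type benchmark scenario
#'
#' Simulated single-cell datasets with known cell-type markers: cells are
#' aggregated into (sample, cell type) pseudobulks, one-vs-rest contrasts are
#' enumerated over cell types per dataset, and the matching marker collection
#' provides the ground truth with exactly one true positive per contrast.
#'
#' @param seed Integer seed.
#' @param n_datasets Number of datasets, default 2.
#' @param cell_types Cell-type labels, default 7 types.
#' @param samples Replicates per dataset, default 4.
#' @param cells_per_sample Cells per (sample, type), default 30.
#' @return list with `datasets` (each: `counts`, `samples`, `contrasts`),
#'   `markers`, `truth`, and `scope` (contrast id to dataset).
#' @export
scenario_benchmark1 <- function(seed = 1L, n_datasets = 2,
                                cell_types = paste0("ct", 1:7), samples = 4,
                                cells_per_sample = 30) {
  datasets <- list()
  truth <- list()
  scope <- character()
  markers <- NULL
  for (d in seq_len(n_datasets)) {
    sc <- simulate_cell_counts(cell_types, samples = samples,
                               cells_per_sample = cells_per_sample,
                               seed = seed + d)
    pb <- pseudobulk(sc$counts, sc$meta)
    contrasts <- enumerate_contrasts(pb$samples, mode = "one-vs-rest")
    contrasts$id <- paste0("ds", d, ":", contrasts$id)
    markers <- sc$markers
    truth[[d]] <- build_marker_truth(contrasts, sc$markers)
    scope <- c(scope, stats::setNames(rep(paste0("ds", d), nrow(contrasts)),
                                      contrasts$id))
    datasets[[d]] <- list(counts = pb$counts, samples = pb$samples,
                          contrasts = contrasts)
  }
  list(datasets = datasets, markers = markers,
       truth = do.call(rbind, truth), scope = scope)
}
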