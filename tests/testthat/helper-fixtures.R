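# Shared fixtures, all generated in code.

# Small deterministic count matrix with group structure.
toy_counts <- function(n_genes = 50, n_per_group = 4, seed = 11,
                       mu = 100, size = 5) {
  set.seed(seed)
  n <- 2 * n_per_group
  m <- matrix(rnbinom(n_genes * n, mu = mu, size = size), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  storage.mode(m) <- "integer"
  list(counts = m,
       samples = data.frame(sample = colnames(m),
                            group = rep(c("A", "B"), each = n_per_group),
                            stringsAsFactors = FALSE),
       contrasts = data.frame(id = "A_vs_B", numerator = "A",
                              denominator = "B", stringsAsFactors = FALSE))
}

# Write a small count TSV and return its path.
toy_counts_file <- function(counts, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  write_count_matrix(counts, path)
  path
}

# A DE table with given per-gene stats for one pipeline/contrast.
de_table <- function(pipeline, stats, contrast = "c1", padj = NULL) {
  data.frame(pipeline = pipeline, contrast = contrast, gene = names(stats),
             lfc = unname(stats), stat = unname(stats),
             p = rep(0.5, length(stats)),
             padj = padj %||% rep(0.5, length(stats)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force AUROC: average over all positive-negative pairs, ties count 1/2.
auroc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exact one-sided Wilcoxon p by enumerating all label assignments.
wilcoxon_exact_enum <- function(a, b, alternative = "less") {
  pooled <- c(a, b)
  n <- length(pooled)
  idx <- utils::combn(n, length(a))
  r <- rank(pooled)
  w_obs <- sum(r[seq_along(a)])
  w_all <- apply(idx, 2L, function(i) sum(r[i]))
  if (alternative == "less") mean(w_all <= w_obs) else mean(w_all >= w_obs)
}
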