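test_that("the pipeline grid has exactly 12 members", {
  grid <- pipeline_grid()
  expect_identical(nrow(grid), 12L)
  expect_identical(sort(unique(grid$filtering)), c("filtered", "unfiltered"))
  expect_length(unique(grid$method), 6L)
  expect_false(anyDuplicated(grid$id) > 0)
})

test_that("moderated fit recovers group-mean differences and the shrinkage formula", {
  set.seed(51)
  n <- 60
  design <- cbind(A = rep(c(1, 0), each = 3), B = rep(c(0, 1), each = 3))
  # heterogeneous per-gene variances so the empirical-Bayes prior df is finite
  gene_sd <- exp(rnorm(n, 0, 0.7))
  values <- matrix(rnorm(n * 6, mean = 5, sd = rep(gene_sd, 6)), nrow = n,
                   dimnames = list(sprintf("g%02d", 1:n), sprintf("s%d", 1:6)))
  cv <- c(A = 1, B = -1)
  fit <- fit_moderated_lm(values, design, cv)

  # OLS identity: lfc is the difference of group means
  expect_equal(fit$lfc, unname(rowMeans(values[, 1:3]) - rowMeans(values[, 4:6])),
               tolerance = 1e-10)

  # dual route: reconstruct the moderated t from independently computed
  # residual variances, the contrast's unscaled variance and the reported
  # prior (d0, s0^2)
  d0 <- attr(fit, "d0")
  s0sq <- attr(fit, "s0sq")
  vc <- drop(t(cv) %*% solve(crossprod(design)) %*% cv)
  dg <- 6 - qr(design)$rank
  s2 <- apply(values, 1, function(y) sum(lm.fit(design, y)$residuals^2) / dg)
  s2_post <- (d0 * s0sq + dg * s2) / (d0 + dg)
  expect_equal(fit$stat, unname(fit$lfc / sqrt(s2_post * vc)), tolerance = 1e-8)
  expect_equal(fit$df, rep(d0 + dg, n), tolerance = 1e-8)
  # p-values come from the t distribution on d0 + dg df
  expect_equal(fit$p, 2 * pt(abs(fit$stat), d0 + dg, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("equal residual variances make the moderated t the ordinary t", {
  # identical residual patterns across genes => identical s_g^2 => no shrinkage
  design <- cbind(A = rep(c(1, 0), each = 4), B = rep(c(0, 1), each = 4))
  resid <- c(-1, 0.5, 0.2, 0.3, -0.6, 0.9, -0.4, 0.1)
  means <- seq(0, 3, length.out = 10)
  values <- t(vapply(means, function(m)
    m * design[, "A"] + resid, numeric(8)))
  dimnames(values) <- list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8))
  fit <- fit_moderated_lm(values, design, c(A = 1, B = -1))
  ordinary_t <- vapply(seq_len(10), function(i) {
    y <- values[i, ]
    f <- lm(y ~ 0 + design)
    unname(coef(f)[1] - coef(f)[2]) /
      (summary(f)$sigma * sqrt(0.25 + 0.25))
  }, numeric(1))
  expect_equal(fit$stat, ordinary_t, tolerance = 1e-8)
})

test_that("degenerate all-constant genes report stat 0 and p 1", {
  design <- cbind(1, rep(0:1, each = 3))
  values <- matrix(3, nrow = 4, ncol = 6,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  fit <- fit_moderated_lm(values, design, c(0, 1))
  expect_true(all(fit$stat == 0))
  expect_true(all(fit$p == 1))
})

test_that("NB Wald statistics match an independent GLM fit at the same dispersion", {
  set.seed(9)
  n <- 10
  mu <- c(50, 200, 20, 400, 100, 30, 250, 80, 60, 150)
  counts <- matrix(rnbinom(n * 8, mu = rep(mu, 8), size = 5), nrow = n,
                   dimnames = list(paste0("g", 1:n), paste0("s", 1:8)))
  counts[2, 5:8] <- counts[2, 5:8] * 3L
  samples <- data.frame(sample = paste0("s", 1:8),
                        group = rep(c("A", "B"), each = 4))
  ct <- data.frame(id = "A_vs_B", numerator = "A", denominator = "B")
  de <- deconcord:::run_wald_engine(counts, samples, ct)

  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, data.frame(group = factor(samples$group), row.names = samples$sample),
    ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  sf <- DESeq2::sizeFactors(dds)
  disp <- DESeq2::dispersions(dds)
  oracle <- vapply(seq_len(n), function(i) {
    g <- factor(samples$group, levels = c("B", "A"))
    f <- glm(counts[i, ] ~ g + offset(log(sf)),
             family = MASS::negative.binomial(theta = 1 / disp[i]),
             control = glm.control(epsilon = 1e-12, maxit = 100))
    s <- summary(f, dispersion = 1)$coefficients
    s["gA", "Estimate"] / s["gA", "Std. Error"]
  }, numeric(1))
  expect_equal(de$stat, oracle, tolerance = 1e-5)
})

test_that("count engines obey symmetry and antisymmetry", {
  sim <- toy_counts(n_genes = 60, seed = 13)
  # identical columns across groups: everything null
  m <- sim$counts
  m[, 5:8] <- m[, 1:4]
  ct <- sim$contrasts
  # zero up to the engines' IRLS convergence tolerance
  for (engine in c("run_wald_engine", "run_ql_engine")) {
    de <- getFromNamespace(engine, "deconcord")(m, sim$samples, ct)
    expect_true(all(abs(de$lfc) < 1e-4), label = engine)
    expect_true(all(abs(de$stat) < 1e-4), label = engine)
  }
  # swapping numerator and denominator negates lfc and stat
  ct_rev <- data.frame(id = "B_vs_A", numerator = "B", denominator = "A")
  for (engine in c("run_wald_engine", "run_ql_engine")) {
    fwd <- getFromNamespace(engine, "deconcord")(sim$counts, sim$samples, ct)
    rev <- getFromNamespace(engine, "deconcord")(sim$counts, sim$samples, ct_rev)
    expect_equal(fwd$lfc, -rev$lfc, tolerance = 1e-8, label = engine)
    expect_equal(fwd$stat, -rev$stat, tolerance = 1e-6, label = engine)
  }
})

test_that("the QL engine reports sign(lfc) * sqrt(F) as its t-like statistic", {
  sim <- toy_counts(n_genes = 80, seed = 17)
  de <- deconcord:::run_ql_engine(sim$counts, sim$samples, sim$contrasts)
  y <- edgeR::DGEList(sim$counts, group = factor(sim$samples$group))
  y <- edgeR::calcNormFactors(y)
  design <- cbind(A = rep(c(1, 0), each = 4), B = rep(c(0, 1), each = 4))
  y <- edgeR::estimateDisp(y, design)
  qlf <- edgeR::glmQLFTest(edgeR::glmQLFit(y, design), contrast = c(1, -1))
  expect_equal(de$stat^2, unname(qlf$table$F), tolerance = 1e-8)
  expect_equal(sign(de$stat), sign(de$lfc))
  # ranking by |stat| is the F ranking
  expect_identical(order(-abs(de$stat)), order(-qlf$table$F))
  expect_equal(de$p, unname(qlf$table$PValue), tolerance = 1e-10)
})

test_that("the grid emits one block per pipeline with BH adjustment within contrast", {
  sim <- toy_counts(n_genes = 100, seed = 19, mu = 80)
  de <- run_pipeline_grid(sim$counts, sim$samples, sim$contrasts,
                          pipelines = pipeline_grid("unfiltered"))
  expect_setequal(unique(de$pipeline), pipeline_grid("unfiltered")$id)
  one <- de[de$pipeline == "unfiltered-tmm-limma", ]
  expect_identical(nrow(one), 100L)
  # BH: padj monotone in p, bounded by 1, >= p
  for (pl in unique(de$pipeline)) {
    blk <- de[de$pipeline == pl, ]
    expect_equal(blk$padj, p.adjust(blk$p, "BH"), tolerance = 1e-12)
    expect_true(all(blk$padj >= blk$p - 1e-12 & blk$padj <= 1))
  }
  # sign convention holds for every engine
  nz <- de$lfc != 0
  expect_true(all(sign(de$stat[nz]) == sign(de$lfc[nz]) | de$stat[nz] == 0))
})

test_that("filtered pipelines only differ by absent genes and engines are gene-order invariant", {
  sim <- simulate_bulk_counts(250, c(A = 4, B = 4), dispersion = 0.2,
                              low_count_fraction = 0.4, seed = 23)
  ct <- enumerate_contrasts(sim$samples)
  grid <- pipeline_grid(methods = "tmm-limma")
  de <- run_pipeline_grid(sim$counts, sim$samples, ct, pipelines = grid)
  genes_f <- de$gene[de$pipeline == "filtered-tmm-limma"]
  genes_u <- de$gene[de$pipeline == "unfiltered-tmm-limma"]
  expect_true(all(genes_f %in% genes_u))
  expect_lt(length(genes_f), length(genes_u))

  perm <- sample(nrow(sim$counts))
  de_p <- run_pipeline_grid(sim$counts[perm, ], sim$samples, ct,
                            pipelines = pipeline_grid("unfiltered", "tmm-limma"))
  de_u <- de[de$pipeline == "unfiltered-tmm-limma", ]
  expect_equal(de_p$stat[match(de_u$gene, de_p$gene)], de_u$stat,
               tolerance = 1e-10)
})

test_that("one-vs-rest contrasts run through every engine type", {
  set.seed(29)
  sheet <- data.frame(sample = sprintf("s%02d", 1:12),
                      group = rep(c("A", "B", "C"), each = 4))
  m <- matrix(rnbinom(80 * 12, mu = 60, size = 5), nrow = 80,
              dimnames = list(sprintf("g%02d", 1:80), sheet$sample))
  storage.mode(m) <- "integer"
  ct <- enumerate_contrasts(sheet, mode = "one-vs-rest")
  de <- run_pipeline_grid(m, sheet, ct,
                          pipelines = pipeline_grid("unfiltered",
                                                    c("voom-limma", "edger", "deseq2")))
  expect_setequal(unique(de$contrast), ct$id)
  expect_identical(nrow(de), 80L * 3L * 3L)
})

test_that("all engines are near-uniform under the global null", {
  reps <- 5
  frac <- sapply(c("tmm-limma", "edger", "deseq2"), function(m) {
    p <- unlist(lapply(seq_len(reps), function(r) {
      sim <- simulate_bulk_counts(800, c(A = 5, B = 5), dispersion = 0.2,
                                  low_count_fraction = 0, seed = 100 + r)
      de <- run_pipeline_grid(sim$counts, sim$samples,
                              enumerate_contrasts(sim$samples),
                              pipelines = pipeline_grid("unfiltered", m))
      de$p
    }))
    mean(p < 0.05)
  })
  expect_true(all(frac >= 0.03 & frac <= 0.08),
              label = paste(names(frac), round(frac, 4), collapse = "; "))
})

test_that("all engines rank planted strong effects at the top", {
  planted <- gene_ids(1000)[1:100]
  sim <- simulate_bulk_counts(
    1000, c(A = 5, B = 5), dispersion = 0.2, low_count_fraction = 0,
    lfc_map = setNames(rep(2, 100), planted), seed = 202)
  ct <- enumerate_contrasts(sim$samples)
  for (m in c("tmm-limma", "vsn-limma", "voom-limma", "log2quant-limma",
              "edger", "deseq2")) {
    de <- run_pipeline_grid(sim$counts, sim$samples, ct,
                            pipelines = pipeline_grid("unfiltered", m))
    top <- de$gene[order(-abs(de$stat))][1:200]
    expect_gte(mean(planted %in% top), 0.9)
  }
})
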