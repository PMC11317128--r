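test_that("pseudobulk sums member cells and applies the quality filters", {
  genes <- sprintf("g%02d", 1:5)
  mk_cells <- function(n, mu) matrix(rpois(5 * n, mu), nrow = 5)
  set.seed(91)
  # type T1 in sample s1: 12 healthy cells; type T2: only 9 cells (dropped);
  # type T3: 12 cells but nearly empty (total < 1000, dropped)
  cells <- cbind(mk_cells(12, 30), mk_cells(9, 30), mk_cells(12, 1))
  rownames(cells) <- genes
  colnames(cells) <- sprintf("c%02d", 1:33)
  meta <- data.frame(cell = colnames(cells), sample = "s1",
                     cell_type = rep(c("T1", "T2", "T3"), times = c(12, 9, 12)))
  pb <- pseudobulk(cells, meta)
  expect_identical(colnames(pb$counts), "s1|T1")
  expect_setequal(pb$dropped, c("s1|T2", "s1|T3"))
  expect_identical(unname(pb$counts[, 1]),
                   as.integer(rowSums(cells[, 1:12])))

  # a 3-cell pseudobulk with per-gene counts 1,2,3 sums to 6 per gene
  tiny <- matrix(rep(1:3, each = 2), nrow = 2,
                 dimnames = list(c("ga", "gb"), c("x1", "x2", "x3")))
  pb2 <- pseudobulk(tiny, data.frame(cell = colnames(tiny), sample = "s",
                                     cell_type = "T"),
                    min_cells = 1, min_counts = 1)
  expect_identical(unname(pb2$counts[, 1]), c(6L, 6L))

  # unlabeled cells are discarded before aggregation
  meta_na <- meta
  meta_na$cell_type[1:2] <- NA
  pb3 <- pseudobulk(cells, meta_na, min_cells = 1, min_counts = 1)
  expect_identical(pb3$samples$n_cells[pb3$samples$group == "T1"], 10L)

  expect_error(pseudobulk(cells, meta, min_cells = 50),
               class = "deconcord_validation_error")
})

test_that("marker truth assigns exactly one positive per contrast", {
  types <- paste0("ct", 1:7)
  markers <- geneset_collection(data.frame(
    set = rep(types, each = 5), gene = sprintf("g%03d", 1:35)))
  sheet <- data.frame(sample = sprintf("s%02d", 1:14), group = rep(types, 2))
  ct <- enumerate_contrasts(sheet, mode = "one-vs-rest")
  truth <- build_marker_truth(ct, markers)
  per_ct <- tapply(truth$label, truth$contrast, sum)
  expect_true(all(per_ct == 1))
  expect_identical(nrow(truth), 7L * 7L)
  expect_identical(sum(truth$label == 0) / length(per_ct), 6)

  two <- build_marker_truth(ct[1:2, ],
                            geneset_collection(data.frame(
                              set = ct$numerator[1:2],
                              gene = sprintf("m%d", 1:10))))
  expect_identical(sum(two$label), 2L)

  bad_ct <- ct
  bad_ct$numerator[1] <- "unknown_type"
  err <- tryCatch(build_marker_truth(bad_ct, markers), error = identity)
  expect_s3_class(err, "deconcord_validation_error")
  expect_match(conditionMessage(err), "unknown_type")
})

test_that("TF assignment is greedy by score with global uniqueness", {
  coll <- geneset_collection(data.frame(
    set = rep(sprintf("tf%d", 1:6), each = 5), gene = sprintf("g%03d", 1:30)),
    name = "tf")
  binding <- data.frame(
    cell_type = c("endo", "peri", "endo", "peri", "endo", "vsmc"),
    tf = c("tf1", "tf1", "tf2", "tf3", "tf4", "tf9"),
    score = c(5, 3, 4, 2, 1, 10))
  asg <- assign_tf_markers(binding, k = 10, coll = coll)
  # tf9 absent from the regulons: discarded before assignment
  expect_false("tf9" %in% asg$tf)
  # tf1 claimed by the higher-scoring cell type only
  expect_identical(asg$cell_type[asg$tf == "tf1"], "endo")
  expect_false(anyDuplicated(asg$tf) > 0)
  # claimed-elsewhere TFs leave a cell type with fewer markers
  expect_identical(sum(asg$cell_type == "peri"), 1L)

  # cap at k per cell type; no-conflict case fills min(k, available)
  b2 <- data.frame(cell_type = rep(c("a", "b"), each = 3),
                   tf = sprintf("tf%d", 1:6), score = 6:1)
  asg2 <- assign_tf_markers(b2, k = 2, coll = coll)
  expect_identical(unname(table(asg2$cell_type)["a"]), 2L)
  expect_identical(unname(table(asg2$cell_type)["b"]), 2L)

  # row order of the binding table is irrelevant
  set.seed(93)
  asg3 <- assign_tf_markers(binding[sample(nrow(binding)), ], k = 10, coll = coll)
  expect_identical(asg3, asg)

  expect_error(assign_tf_markers(binding[binding$tf == "tf9", ], coll = coll),
               class = "deconcord_validation_error")
})

test_that("pooled ranking concatenates contrasts deterministically", {
  set.seed(95)
  contrasts <- sprintf("c%d", 1:6)
  cands <- sprintf("set%d", 1:7)
  truth <- expand.grid(contrast = contrasts, candidate = cands,
                       stringsAsFactors = FALSE)
  truth$label <- as.integer(truth$candidate == "set1")
  act <- expand.grid(contrast = contrasts, set = cands,
                     stringsAsFactors = FALSE)
  act$pipeline <- "p1"
  act$score <- rnorm(nrow(act))
  ranked <- pooled_rank(act, truth)
  expect_identical(nrow(ranked), 42L)
  expect_true(all(diff(ranked$score) <= 0))
  # permuting input rows changes nothing
  ranked2 <- pooled_rank(act[sample(nrow(act)), ], truth)
  expect_identical(ranked, ranked2)
  # single contrast: pooling is the identity
  r1 <- pooled_rank(act[act$contrast == "c1", ],
                    truth[truth$contrast == "c1", ])
  expect_identical(nrow(r1), 7L)
  # missing scores are an error that names the gap
  expect_error(pooled_rank(act[-1, ], truth), class = "deconcord_validation_error")
})

test_that("AUROC matches brute-force pair counting, including ties", {
  expect_identical(auroc(c(1, 0, 0), c(0.9, 0.5, 0.8)), 1)
  expect_identical(auroc(rep(c(1, 0), 4), rep(1, 8)), 0.5)
  set.seed(97)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    labels <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(4, n, replace = TRUE)  # forces ties
    expect_equal(auroc(labels, scores), auroc_bruteforce(labels, scores))
    # reversing scores mirrors the value
    expect_equal(auroc(labels, -scores), 1 - auroc(labels, scores))
  }
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), class = "deconcord_validation_error")
})

test_that("AUPRC integrates the step curve with atomic tie blocks", {
  expect_identical(auprc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(auprc(c(0, 1), c(0.9, 0.1)), 0.5)
  # perfect ranking is 1 at any prevalence
  for (np in 1:3)
    expect_equal(auprc(c(rep(1, np), rep(0, 6 - np)), 6:1), 1)
  # all-tied scores give precision = prevalence everywhere
  expect_equal(auprc(c(1, 0, 0, 1), rep(2, 4)), 0.5)
  # hand-computed 4-instance case: ranking (1, 0, 1, 0)
  # precision at the two positives: 1/1 and 2/3
  expect_equal(auprc(c(1, 0, 1, 0), c(4, 3, 2, 1)), (1 + 2 / 3) / 2)
})

test_that("perturbation truth labels mapped sets per contrast", {
  ct <- data.frame(id = sprintf("p%02d_vs_control", 1:5),
                   perturbation = sprintf("pert%d", 1:5))
  mapping <- data.frame(perturbation = sprintf("pert%d", 1:4),
                        gene_set = c("hmA", "hmB", "hmC", "hmA"))
  expect_message(truth <- perturbation_truth(ct, mapping), "excluding 1")
  expect_setequal(unique(truth$candidate), c("hmA", "hmB", "hmC"))
  expect_identical(sum(truth$label[truth$contrast == "p01_vs_control"]), 1L)
  # a perturbation mapped to two sets has two positives
  m2 <- rbind(mapping, data.frame(perturbation = "pert1", gene_set = "hmB"))
  t2 <- perturbation_truth(ct, m2)
  expect_identical(sum(t2$label[t2$contrast == "p01_vs_control"]), 2L)
  expect_error(perturbation_truth(ct, mapping[0, ]),
               class = "deconcord_validation_error")
})

test_that("benchmark_score reports per-pipeline AUROC/AUPRC over pooled instances", {
  set.seed(99)
  contrasts <- sprintf("c%d", 1:4)
  cands <- sprintf("s%d", 1:6)
  truth <- expand.grid(contrast = contrasts, candidate = cands,
                       stringsAsFactors = FALSE)
  truth$label <- as.integer(truth$candidate == "s1")
  act <- do.call(rbind, lapply(c("good", "bad"), function(pl) {
    a <- expand.grid(contrast = contrasts, set = cands, stringsAsFactors = FALSE)
    a$pipeline <- pl
    a$score <- if (pl == "good") 5 * (a$set == "s1") + rnorm(nrow(a), 0, 0.1)
               else rnorm(nrow(a))
    a
  }))
  rep <- benchmark_score(act, truth, benchmark_id = "markers")
  expect_identical(rep$auroc[rep$pipeline == "good"], 1)
  expect_identical(rep$auprc[rep$pipeline == "good"], 1)
  expect_lt(rep$auroc[rep$pipeline == "bad"], 1)
  expect_identical(unique(rep$n_pos), 4L)
  expect_identical(unique(rep$n_neg), 20L)
})
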