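#' The pipeline grid
#'
#' Two filtering arms crossed with six normalization/differential-expression
#' methods give the full grid of 12 alternative pipelines. Four methods
#' normalise the counts and fit empirical-Bayes moderated-t linear models
#' (TMM, vsn-like glog, voom, log-quantile); the remaining two model raw
#' counts directly with negative-binomial GLMs (quasi-likelihood F and Wald).
#'
#' @param filtering Subset of `c("filtered", "unfiltered")`.
#' @param methods Subset of `c("tmm-limma", "vsn-limma", "voom-limma",
#'   "log2quant-limma", "edger", "deseq2")`.
#' @return data.frame with columns `id`, `filtering`, `method`.
#' @examples
#' nrow(pipeline_grid())  # 12
#' @export
pipeline_grid <- function(filtering = c("filtered", "unfiltered"),
                          methods = c("tmm-limma", "vsn-limma", "voom-limma",
                                      "log2quant-limma", "edger", "deseq2")) {
  filtering <- match.arg(filtering, several.ok = TRUE)
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- expand.grid(method = methods, filtering = filtering,
                      stringsAsFactors = FALSE)
  data.frame(id = paste(grid$filtering, grid$method, sep = "-"),
             filtering = grid$filtering, method = grid$method,
             stringsAsFactors = FALSE)
}

# Build the joint group design (one column per group, covariates additive).
group_design <- function(samples, covariates = NULL) {
  group <- factor(samples$group)
  if (is.null(covariates)) {
    design <- stats::model.matrix(~ 0 + group)
    colnames(design) <- levels(group)
  } else {
    covs <- samples[, covariates, drop = FALSE]
    covs[] <- lapply(covs, factor)
    design <- stats::model.matrix(~ 0 + group + .,
                                  data = cbind(data.frame(group = group), covs))
    colnames(design)[seq_along(levels(group))] <- levels(group)
  }
  design
}

# Two-level design for a one-vs-rest contrast: coefficient 2 is target - rest.
rest_design <- function(samples, numerator, covariates = NULL) {
  grp <- factor(ifelse(samples$group == numerator, "target", "rest"),
                levels = c("rest", "target"))
  if (is.null(covariates)) {
    stats::model.matrix(~ grp)
  } else {
    covs <- samples[, covariates, drop = FALSE]
    covs[] <- lapply(covs, factor)
    stats::model.matrix(~ grp + ., data = cbind(data.frame(grp = grp), covs))
  }
}

# Numeric contrast vector (numerator - denominator) over a joint design.
contrast_vector <- function(design, numerator, denominator) {
  v <- stats::setNames(numeric(ncol(design)), colnames(design))
  if (!all(c(numerator, denominator) %in% colnames(design)))
    stop_validation("contrast groups '%s', '%s' not in design",
                    numerator, denominator)
  v[numerator] <- 1
  v[denominator] <- -1
  v
}

#' Empirical-Bayes moderated-t linear model for one contrast
#'
#' Per-gene (optionally precision-weighted) least-squares fits; residual
#' variances are shrunk towards a common prior,
#' `s2_post = (d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)`, and the contrast's
#' t-statistic uses the shrunk variance with `d0 + d_g` degrees of freedom.
#' Backed by `limma::lmFit`/`eBayes`.
#'
#' @param values Normalized genes x samples matrix.
#' @param design Design matrix.
#' @param contrast Numeric contrast vector over the design columns (or a
#'   single coefficient name).
#' @param weights Optional positive precision-weight matrix (voom).
#' @return data.frame with `gene`, `lfc`, `stat`, `p`, `df`. Degenerate genes
#'   (zero residual variance everywhere) get `stat = 0`, `p = 1`.
#' @export
fit_moderated_lm <- function(values, design, contrast, weights = NULL) {
  if (ncol(values) != nrow(design)) stop_validation("design rows must match samples")
  if (ncol(values) - qr(design)$rank < 1L)
    stop_validation("no residual degrees of freedom")
  fit <- limma::lmFit(values, design, weights = weights)
  if (is.character(contrast)) {
    cv <- stats::setNames(numeric(ncol(design)), colnames(design))
    cv[contrast] <- 1
    contrast <- cv
  }
  fit2 <- limma::contrasts.fit(fit, contrasts = matrix(contrast, ncol = 1L))
  fit2 <- limma::eBayes(fit2)
  lfc <- fit2$coefficients[, 1L]
  stat <- fit2$t[, 1L]
  p <- fit2$p.value[, 1L]
  bad <- !is.finite(stat) | !is.finite(p)
  # all-constant genes: zero residual variance and zero effect
  bad <- bad | (fit2$sigma < 1e-12 & abs(lfc) < 1e-10)
  stat[bad] <- 0
  p[bad] <- 1
  out <- data.frame(gene = rownames(values), lfc = unname(lfc),
                    stat = unname(stat), p = unname(p),
                    df = unname(rep_len(fit2$df.total, nrow(values))),
                    stringsAsFactors = FALSE)
  # estimated empirical-Bayes prior, exposed for auditing the shrinkage
  attr(out, "d0") <- unname(fit2$df.prior[1L])
  attr(out, "s0sq") <- unname(fit2$s2.prior[1L])
  attr(out, "s2_post") <- unname(fit2$s2.post)
  out
}

# Normalized values (and weights) for a limma-path method; voom depends on
# the design, the other transforms do not.
normalize_for_method <- function(method, counts, design) {
  switch(method,
    "tmm-limma" = log_cpm(counts, tmm_factors(counts)),
    "vsn-limma" = glog_vst(counts),
    "log2quant-limma" = quantile_normalize_log(counts),
    "voom-limma" = voom_transform(counts, design, tmm_factors(counts)),
    stop("unknown limma-path method: ", method))
}

# One limma-path method over a set of contrasts -> long data.frame.
run_limma_engine <- function(counts, samples, contrasts, method,
                             covariates = NULL) {
  out <- vector("list", nrow(contrasts))
  simple <- contrasts$denominator != "rest"
  if (any(simple)) {
    design <- group_design(samples, covariates)
    norm <- normalize_for_method(method, counts, design)
    for (i in which(simple)) {
      cv <- contrast_vector(design, contrasts$numerator[i], contrasts$denominator[i])
      res <- fit_moderated_lm(norm$values, design, cv, weights = norm$weights)
      res$contrast <- contrasts$id[i]
      out[[i]] <- res
    }
  }
  for (i in which(!simple)) {
    design <- rest_design(samples, contrasts$numerator[i], covariates)
    norm <- normalize_for_method(method, counts, design)
    res <- fit_moderated_lm(norm$values, design, "grptarget", weights = norm$weights)
    res$contrast <- contrasts$id[i]
    out[[i]] <- res
  }
  do.call(rbind, out)
}

# Negative-binomial Wald engine (DESeq2): median-of-ratios size factors,
# trend-shrunk dispersions, per-gene NB GLM, Wald stat = lfc / SE treated as
# t-like. Independent filtering and outlier handling are disabled so every
# gene entering the engine is reported.
run_wald_engine <- function(counts, samples, contrasts, covariates = NULL) {
  run_one <- function(col_data, design_formula, extract) {
    mode(counts) <- "integer"
    dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts,
                                          colData = col_data,
                                          design = design_formula)
    dds <- tryCatch(DESeq2::estimateSizeFactors(dds),
                    error = function(e)
                      DESeq2::estimateSizeFactors(dds, type = "poscounts"))
    dds <- tryCatch(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)),
                    error = function(e)
                      suppressMessages(DESeq2::DESeq(dds, quiet = TRUE,
                                                     fitType = "mean")))
    extract(dds)
  }
  tidy_results <- function(res, contrast_id) {
    lfc <- res$log2FoldChange
    stat <- res$stat
    p <- res$pvalue
    bad <- !is.finite(lfc) | !is.finite(stat) | !is.finite(p)
    lfc[bad] <- 0; stat[bad] <- 0; p[bad] <- 1
    data.frame(gene = rownames(res), lfc = lfc, stat = stat, p = p,
               df = NA_real_, contrast = contrast_id, stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(contrasts))
  simple <- contrasts$denominator != "rest"
  if (any(simple)) {
    col_data <- data.frame(group = factor(samples$group), row.names = samples$sample)
    form <- ~ group
    if (!is.null(covariates)) {
      for (cv in covariates) col_data[[cv]] <- factor(samples[[cv]])
      form <- stats::as.formula(paste("~", paste(c(covariates, "group"), collapse = " + ")))
    }
    rows <- run_one(col_data, form, function(dds) {
      lapply(which(simple), function(i) {
        res <- DESeq2::results(dds,
                               contrast = c("group", contrasts$numerator[i],
                                            contrasts$denominator[i]),
                               independentFiltering = FALSE, cooksCutoff = FALSE)
        tidy_results(res, contrasts$id[i])
      })
    })
    out[which(simple)] <- rows
  }
  for (i in which(!simple)) {
    col_data <- data.frame(
      grp = factor(ifelse(samples$group == contrasts$numerator[i], "target", "rest"),
                   levels = c("rest", "target")),
      row.names = samples$sample)
    form <- ~ grp
    if (!is.null(covariates)) {
      for (cv in covariates) col_data[[cv]] <- factor(samples[[cv]])
      form <- stats::as.formula(paste("~", paste(c(covariates, "grp"), collapse = " + ")))
    }
    out[[i]] <- run_one(col_data, form, function(dds) {
      res <- DESeq2::results(dds, contrast = c("grp", "target", "rest"),
                             independentFiltering = FALSE, cooksCutoff = FALSE)
      tidy_results(res, contrasts$id[i])
    })
  }
  do.call(rbind, out)
}

# Negative-binomial quasi-likelihood engine (edgeR): TMM factors, trended +
# tagwise dispersions, QL F-test per 1-df contrast; the reported statistic is
# sign(lfc) * sqrt(F) so that all engines emit t-like values.
run_ql_engine <- function(counts, samples, contrasts, covariates = NULL) {
  fit_for_design <- function(design) {
    y <- edgeR::DGEList(counts, group = factor(samples$group))
    y <- edgeR::calcNormFactors(y)
    y <- edgeR::estimateDisp(y, design)
    edgeR::glmQLFit(y, design)
  }
  tidy_ql <- function(qlf, contrast_id) {
    tab <- qlf$table
    stat <- sign(tab$logFC) * sqrt(pmax(tab$F, 0))
    p <- tab$PValue
    bad <- !is.finite(stat) | !is.finite(p)
    stat[bad] <- 0; p[bad] <- 1
    data.frame(gene = rownames(tab), lfc = tab$logFC, stat = stat, p = p,
               df = NA_real_, contrast = contrast_id, stringsAsFactors = FALSE)
  }
  out <- vector("list", nrow(contrasts))
  simple <- contrasts$denominator != "rest"
  if (any(simple)) {
    design <- group_design(samples, covariates)
    fit <- fit_for_design(design)
    for (i in which(simple)) {
      cv <- contrast_vector(design, contrasts$numerator[i], contrasts$denominator[i])
      out[[i]] <- tidy_ql(edgeR::glmQLFTest(fit, contrast = cv), contrasts$id[i])
    }
  }
  for (i in which(!simple)) {
    design <- rest_design(samples, contrasts$numerator[i], covariates)
    fit <- fit_for_design(design)
    out[[i]] <- tidy_ql(edgeR::glmQLFTest(fit, coef = 2L), contrasts$id[i])
  }
  do.call(rbind, out)
}

#' Run the pipeline grid
#'
#' Executes every requested pipeline on one count matrix: the expression
#' filter is applied for `filtered` pipelines, each method produces per-gene
#' effect sizes, t-like statistics and p-values for every contrast, and
#' p-values are BH-adjusted within each (pipeline, contrast). Genes removed by
#' filtering are absent from that pipeline's rows. A failure of one engine on
#' one contrast is recorded as a warning; the remaining contrasts proceed.
#'
#' @param counts Count matrix (genes x samples, unique gene ids).
#' @param samples Sample sheet.
#' @param contrasts Contrast table from [enumerate_contrasts()].
#' @param pipelines Pipeline table from [pipeline_grid()].
#' @param fp [filter_params()] for the filtered arm.
#' @param covariates Optional character vector of sample-sheet columns entering
#'   every design additively.
#' @return Long data.frame: `pipeline`, `contrast`, `gene`, `lfc`, `stat`,
#'   `p`, `padj`.
#' @export
run_pipeline_grid <- function(counts, samples, contrasts,
                              pipelines = pipeline_grid(),
                              fp = filter_params(), covariates = NULL) {
  assert_count_matrix(counts)
  samples <- align_samples(samples, counts)
  if (nrow(pipelines) == 0L) stop_validation("no pipelines requested")
  if (nrow(contrasts) == 0L) stop_validation("no contrasts to test")
  arms <- list()
  for (flt in unique(pipelines$filtering)) {
    if (flt == "filtered") {
      keep <- expression_filter(counts, samples, fp)
      if (!any(keep)) stop_validation("expression filter removed every gene")
      arms[[flt]] <- counts[keep, , drop = FALSE]
    } else {
      arms[[flt]] <- counts
    }
  }
  res <- vector("list", nrow(pipelines))
  for (j in seq_len(nrow(pipelines))) {
    sub <- arms[[pipelines$filtering[j]]]
    method <- pipelines$method[j]
    tab <- tryCatch({
      if (method == "deseq2") run_wald_engine(sub, samples, contrasts, covariates)
      else if (method == "edger") run_ql_engine(sub, samples, contrasts, covariates)
      else run_limma_engine(sub, samples, contrasts, method, covariates)
    }, error = function(e) {
      warning(sprintf("pipeline %s failed: %s", pipelines$id[j], conditionMessage(e)))
      NULL
    })
    if (is.null(tab)) next
    tab$pipeline <- pipelines$id[j]
    split_p <- split(seq_len(nrow(tab)), tab$contrast)
    tab$padj <- NA_real_
    for (rows in split_p) tab$padj[rows] <- stats::p.adjust(tab$p[rows], "BH")
    res[[j]] <- tab[, c("pipeline", "contrast", "gene", "lfc", "stat", "p", "padj")]
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop_validation("every pipeline failed")
  rownames(out) <- NULL
  out
}
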