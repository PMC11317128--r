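# Normalization transforms feeding the moderated-t engine. Each returns a
# list(values, weights, method): `values` is the genes x samples matrix handed
# to the linear model, `weights` (voom only) are per-observation precision
# weights.

#' Trimmed-mean-of-M-values scaling factors
#'
#' Composition-robust scaling factors: per sample, a doubly trimmed (30% on
#' log-ratios, 5% on average log-intensity), precision-weighted mean of
#' log2 ratios against a reference sample, normalised so the factors multiply
#' to one. Computed by `edgeR::calcNormFactors`.
#'
#' @param counts Count matrix, at least two samples, positive library sizes.
#' @param trim_m Trim fraction on log-ratios (default 0.3).
#' @param trim_a Trim fraction on average log-intensity (default 0.05).
#' @return Named positive numeric vector of per-sample factors, product 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  assert_count_matrix(counts)
  if (ncol(counts) < 2L) stop_validation("TMM needs at least two samples")
  if (any(colSums(counts) <= 0)) stop_validation("sample with zero library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(f, colnames(counts))
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`; with the
#' default prior of 0.5 this is the standard offset log-CPM that stays finite
#' at zero counts.
#'
#' @param counts Count matrix.
#' @param factors Per-sample scaling factors (default all 1).
#' @param prior Prior count added to the numerator (half of it, doubled, to
#'   the library size), default 0.5.
#' @return list(values, weights = NULL, method = "log-cpm").
#' @export
log_cpm <- function(counts, factors = rep(1, ncol(counts)), prior = 0.5) {
  assert_count_matrix(counts)
  if (any(factors <= 0)) stop_validation("scaling factors must be positive")
  if (prior <= 0 && any(counts == 0))
    stop_validation("non-positive prior with zero counts")
  eff_lib <- colSums(counts) * factors + 2 * prior
  vals <- t(log2(t(counts + prior) / eff_lib * 1e6))
  list(values = vals, weights = NULL, method = "log-cpm")
}

#' Log quantile normalization
#'
#' `log2(count + 1)` followed by quantile normalization across samples: each
#' column's sorted values are replaced by the across-sample mean of the order
#' statistics, tied values receiving the mean of their target quantiles.
#' Afterwards all columns share the same empirical distribution.
#'
#' @param counts Count matrix.
#' @return list(values, weights = NULL, method = "log2quant").
#' @export
quantile_normalize_log <- function(counts) {
  assert_count_matrix(counts)
  lg <- log2(counts + 1)
  if (ncol(counts) < 2L) {
    warning("single sample: returning log2(count + 1) without quantile step")
    return(list(values = lg, weights = NULL, method = "log2quant"))
  }
  vals <- limma::normalizeBetweenArrays(lg, method = "quantile")
  dimnames(vals) <- dimnames(counts)
  list(values = vals, weights = NULL, method = "log2quant")
}

# Median-of-ratios size factors (geometric-mean reference over genes with
# all-positive counts; falls back to positive-count geometric means when no
# gene is expressed everywhere).
size_factors_mor <- function(counts) {
  logc <- log(counts)
  ok <- rowSums(is.finite(logc)) == ncol(counts)
  if (any(ok)) {
    ref <- rowMeans(logc[ok, , drop = FALSE])
    sf <- apply(logc[ok, , drop = FALSE], 2L, function(x) exp(stats::median(x - ref)))
  } else {
    lp <- logc
    lp[!is.finite(lp)] <- NA
    ref <- rowMeans(lp, na.rm = TRUE)
    keep <- is.finite(ref)
    sf <- apply(lp[keep, , drop = FALSE], 2L, function(x)
      exp(stats::median(x - ref[keep], na.rm = TRUE)))
  }
  sf / exp(mean(log(sf)))
}

#' Variance-stabilizing generalized-log transform (vsn-like)
#'
#' Each sample is calibrated by its median-of-ratios size factor, then a
#' generalized logarithm `h(x) = log2((x + sqrt(x^2 + c^2)) / 2)` is applied,
#' with the single glog parameter `c` chosen by one-dimensional search to
#' minimise the absolute Spearman correlation between row means and row
#' standard deviations of the transformed matrix -- a direct implementation of
#' the variance-stabilization contract. For `x >> c` the transform approaches
#' `log2(x)`; it is strictly monotone within each sample.
#'
#' @param counts Count matrix with at least two genes and two samples.
#' @return list(values, weights = NULL, method = "vsn", c = fitted glog
#'   parameter, size_factors).
#' @export
glog_vst <- function(counts) {
  assert_count_matrix(counts)
  if (nrow(counts) < 2L) stop_validation("vsn-like transform needs >= 2 genes")
  if (ncol(counts) < 2L) stop_validation("vsn-like transform needs >= 2 samples")
  sf <- size_factors_mor(counts)
  x <- sweep(counts, 2L, sf, "/")
  glog2 <- function(x, c) log2((x + sqrt(x^2 + c^2)) / 2)
  objective <- function(logc) {
    h <- glog2(x, exp(logc))
    s <- row_sds(h)
    m <- rowMeans(h)
    if (stats::sd(s) == 0 || stats::sd(m) == 0) return(0)
    abs(stats::cor(m, s, method = "spearman"))
  }
  hi <- max(1, stats::quantile(x, 0.99))
  opt <- stats::optimize(objective, interval = log(c(1e-3, 10 * hi)))
  c_hat <- exp(opt$minimum)
  list(values = glog2(x, c_hat), weights = NULL, method = "vsn",
       c = c_hat, size_factors = sf)
}

#' Mean-variance modelling with precision weights (voom)
#'
#' Log-CPM values plus per-observation precision weights: square-root residual
#' standard deviations from a per-gene group-means fit are smoothed against
#' average log-count by lowess (span 0.5 by default), and each observation is
#' weighted by the inverse fourth power of its predicted square-root standard
#' deviation, with the trend clamped at its boundary values. Backed by
#' `limma::voom`.
#'
#' @param counts Count matrix.
#' @param design Design matrix with at least one residual degree of freedom.
#' @param factors Per-sample scaling factors applied to the library sizes.
#' @param span Lowess span for the mean-variance trend.
#' @return list(values, weights, method = "voom"), weights strictly positive.
#' @export
voom_transform <- function(counts, design, factors = rep(1, ncol(counts)),
                           span = 0.5) {
  if (!is.matrix(counts) || !is.numeric(counts) || anyNA(counts) ||
      any(counts < 0))
    stop_validation("counts must be a non-negative numeric matrix")
  if (nrow(design) != ncol(counts))
    stop_validation("design rows must match samples")
  if (ncol(counts) - qr(design)$rank < 1L)
    stop_validation("voom needs at least one residual degree of freedom")
  v <- limma::voom(counts, design = design,
                   lib.size = colSums(counts) * factors, span = span)
  list(values = v$E, weights = v$weights, method = "voom")
}
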