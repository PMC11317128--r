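---
title: "Measuring how much the choice of RNA-seq pipeline matters downstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring how much the choice of RNA-seq pipeline matters downstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Bulk and pseudobulk RNA-seq analyses chain several method choices: whether to
remove lowly expressed genes, how to normalise, which differential-expression
(DE) engine to use, and how to summarise gene-level results into gene-set
activities. Each step has several defensible options, and while the impact of
these choices on DE tables is well studied, their *cumulative* effect on
downstream functional enrichment — the layer on which biological
interpretation usually rests — is much less visible.

`deconcord` makes that effect measurable. It runs a grid of alternative
end-to-end pipelines on one count matrix, pushes every pipeline through the
same gene-set enrichment, and quantifies (i) how much pipelines agree with
each other, in gene space and in gene-set space, and (ii) how well each
pipeline recovers constructed ground truths.

## The pipeline grid

Two filtering arms are crossed with six normalisation/DE methods, giving 12
pipelines:

* **Filtering**: either the counts are used as-is, or lowly expressed genes
  are removed with the design-aware rule of `edgeR::filterByExpr` (a gene is
  kept if it reaches about `min_count` counts-per-million in at least as many
  samples as the smallest group holds, and `min_total_count` counts overall;
  defaults 10 and 15). The rule deliberately keeps genes expressed in only
  one group.
* **Moderated-t paths**: TMM scaling factors + log-CPM, a variance-stabilising
  generalized-log transform, log-quantile normalisation, or voom precision
  weights — each followed by an empirical-Bayes moderated-t linear model
  (`limma`). Residual variances are shrunk as
  `s2_post = (d0*s0^2 + d_g*s_g^2) / (d0 + d_g)` and the contrast t-statistic
  uses `d0 + d_g` degrees of freedom.
* **Count paths**: a negative-binomial quasi-likelihood F-test (`edgeR`) and a
  negative-binomial Wald test (`DESeq2`), run on raw counts. The QL F is
  converted to a t-like value via `t = sign(lfc) * sqrt(F)` so that every
  pipeline emits a signed, roughly t-distributed statistic; Wald statistics
  are treated as t-like directly.

The vsn-like transform deserves a note: it is implemented here as a
per-sample median-of-ratios calibration followed by a generalized logarithm
`h(x) = log2((x + sqrt(x^2 + c^2)) / 2)` with a single parameter `c` chosen
by one-dimensional search to minimise the absolute Spearman correlation
between per-gene means and standard deviations. This keeps the
variance-stabilisation contract (and the monotone, log-like behaviour for
large counts) with one transparent tuning parameter; it does not reproduce
the full per-sample robust maximum-likelihood calibration of the original
microarray method, which is why we label it "vsn-like".

Contrasts follow a fixed sign convention (numerator minus denominator) and,
for all-pairwise enumeration, a lexicographic ordering so that results are
byte-stable across runs. One-vs-rest contrasts encode the pooled remaining
groups as a single level.

## Signal filtering of contrasts

Near-null comparisons make the downstream agreement metrics meaningless
(rankings of pure noise decorrelate trivially), so contrasts with fewer than
`min_de_genes` genes at BH-adjusted p < `alpha` are removed before the
consistency modules. The method literature states the count threshold (30)
but not the significance rule behind "a DE gene"; we document BH-adjusted
p < 0.05 as the definition and expose both knobs. Whether the rule acts
per-pipeline or globally is also not specified anywhere; the default here
drops a contrast for *all* pipelines when it fails in the majority of them,
so that every pipeline pair is compared on the same contrast set — the
per-pipeline alternative is selectable.

## Enrichment: the univariate linear model

For each gene set, the per-gene t-like statistics `y` are regressed on the
set's membership-weight vector `x` (weights for members — possibly signed,
as in transcription-factor regulons — and 0 for every other gene in that
pipeline's universe), with an intercept. The activity score is the t-value
of the slope; its sign carries the direction of regulation and its magnitude
the strength of evidence. Sets with fewer than 5 matched genes are skipped.
Because non-members enter with x = 0 over the *pipeline's own* gene
universe, filtered and unfiltered pipelines legitimately use different
backgrounds — that is precisely the downstream effect the package measures,
not an artefact to be removed.

## Agreement metrics

* **Rank correlation**: Spearman rho with average ranks, per contrast and
  unordered pipeline pair, on shared genes (gene space) or on gene-set scores
  per resource (set space). Aggregates are unweighted means over contrasts,
  then over pairs.
* **Top/bottom overlap**: `(|top_N ∩ top_N| + |bottom_N ∩ bottom_N|) / 2N`.
  The per-tail form is used because a score of 1 must mean "same top *and*
  same bottom terms"; a pooled-union form would also award 1 to a
  sign-flipped ranking. N follows collection size (pathway-like 3,
  hallmark-like 5, TF-like 15) and, for genes, 5% of the shared universe per
  tail. Ties are broken by item id to keep outputs reproducible.
* **Group comparisons**: one-tailed Wilcoxon rank-sum tests (exact for
  combined n ≤ 20 without ties, tie-corrected normal approximation
  otherwise), BH-corrected across each family of comparisons.

## Benchmarks

Three ground-truth constructions mirror the standard evaluation designs:

1. **Cell-type markers**: single-cell counts are summed into (sample,
   cell-type) pseudobulks (pseudobulks with < 10 cells or < 1000 total counts
   are dropped), one-vs-rest contrasts are enriched against one marker set
   per cell type, and the matching set is the single true positive.
2. **TF assignment**: transcription factors are linked to cell types by
   descending binding score under a global uniqueness constraint (a TF
   belongs to at most one cell type; ties broken by TF id). Greedy
   assignment by score is the simplest rule consistent with "top-k by
   affinity", and it reproduces the characteristic shortened marker lists
   when cell types compete for the same TFs.
3. **Perturbation-to-gene-set maps**: each perturbation contrast's mapped
   set(s) are positives against the other mapped sets.

Instances are pooled across contrasts within a scope (e.g. per study),
ranked by activity score with deterministic tie-breaks, and scored with
tie-aware AUROC (Mann–Whitney form; ties count one half) and AUPRC in the
average-precision formulation with atomic tie blocks — trapezoidal
interpolation of PR curves is optimistically biased, average precision is
not. Chance levels are 0.5 for AUROC and the positive prevalence for AUPRC
(1/7 with seven candidate sets, 1/6 with six).

## What the simulators emulate — and what they do not

All tests and acceptance properties run on synthetic data, so the simulators
are first-class code:

* `simulate_bulk_counts()` draws negative-binomial counts
  (variance `mu + phi*mu^2`) with a log-normal spread of per-gene baselines
  (one doubling around `baseline_mu`), log-normal library factors with a
  given CV (default 0.2), and planted group effects `2^lfc` on named genes.
* A configurable fraction of genes forms a **near-zero stratum**
  (baselines drawn in [0.5, 2]) that is additionally contaminated with
  sporadic bursts: with probability 0.08 an observation's mean jumps to 30,
  independent of group. This is the crucial realism ingredient. A clean
  negative-binomial stratum produces perfectly calibrated t-statistics, and
  filtering then has no mechanism by which to help or hurt; the erratic,
  model-violating behaviour of near-zero genes (dropout and bursts in
  pseudobulk-like data) is exactly what expression filters exist to remove.
  Planted biological effects are restricted to adequately expressed genes,
  matching the premise that the low range is dominated by technical noise.
* `simulate_cell_counts()` plants known marker over-expression per cell type
  and emits the matching marker collection, closing the loop for the
  pseudobulk benchmark.
* `make_toy_collections()` builds desk-scale analogues of the three standard
  resource shapes: 14 pathway footprints with continuous signed weights, 50
  hallmark membership sets, and ~30 signed TF regulons, over a shared
  synthetic gene universe.

Not emulated: real mean-variance trends beyond the NB family, gene-gene
correlation, batch structure, identifier ambiguity, and the empirical
distributions of any real dataset. Passing tests therefore demonstrate that
the machinery behaves as specified and that the filtering phenomena have the
expected direction under controlled conditions — not that any particular
real dataset will show effects of the same size.

## Scenario presets and problem sizes

Three presets drive the property suites, with sizes chosen to finish in
minutes on one CPU while leaving the phenomena visible:

* **Recovery**: one hallmark-like set planted at lfc 2 (5 vs 5 samples, 400
  genes); across 100 seeded replicates, every one of the 12 pipelines should
  rank the planted set first by activity score in at least 95% of runs.
* **Low-signal concordance** (`scenario_low_signal`): two datasets of six
  groups x 4 samples, 800 genes, 40% near-zero stratum, weak planted effects
  (|lfc| 0.5) on a few hallmark sets per group; 30 pairwise contrasts in
  total. Expected direction: the 15 filtered-filtered pipeline pairs show
  higher mean set-space rank correlation than the 15 unfiltered-unfiltered
  pairs (one-sided Wilcoxon p < 0.05).
* **Moderate-signal benchmark** (`scenario_benchmark3`): a control plus 10
  perturbation groups (4 samples each, 800 genes, 50% near-zero stratum);
  60% of perturbations genuinely shift their mapped hallmark (lfc 1.5 on
  expressed member genes), the mapping covers 6 candidate sets. Expected
  direction: filtered pipelines beat unfiltered on pooled AUROC and AUPRC.

Numerical choices worth knowing: log-CPM uses a prior count of 0.5;
quantile normalisation averages tied target quantiles; the glog parameter is
searched on a log scale between 1e-3 and ten times the 99th percentile of
calibrated counts; voom clamps its trend at the boundary rather than
extrapolating; degenerate genes (all-constant) report stat 0 and p 1 instead
of NaN; DESeq2-side results disable independent filtering and outlier
cutoffs so every gene entering an engine is reported; and all-zero genes are
reported with p 1. Dispersion-related moderation is left at the engines'
defaults. Seeds are threaded explicitly through every generator, and no
stage uses hidden randomness, so identical configurations yield
byte-identical outputs.

## Known limitations

Only one enrichment method ships (the univariate linear model) — by design,
since the comparison targets the preprocessing grid. Designs are limited to
one group factor plus optional additive categorical covariates. The count
engines are used with their default shrinkage behaviour; exact
bit-compatibility between this grid and any particular published pipeline
configuration is not a goal. The similarity index needs `2N` items, so very
small collections or heavily filtered universes can make pairs unscorable
(they are skipped with a warning rather than imputed).
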