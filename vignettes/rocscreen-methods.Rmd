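---
title: "Methods: linking cell-line gene expression to drug sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking cell-line gene expression to drug sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rocscreen)
```

## The problem

Large drug-screening projects expose, for hundreds of cancer cell lines, a
response value per (compound, cell line) pair — an IC50 (the concentration
halving viability) and/or an AUDRC (area under the dose-response curve) — next
to transcriptome-wide expression of the same lines. `rocscreen` implements a
uniform pipeline over such cohorts: normalize expression, call each cell line
sensitive or resistant to a compound, rank genes (and gene sets) as expression
biomarkers of that call, integrate significant genes into a random-forest
signature evaluated on held-out lines, and rank the cell-line models
themselves. A synthetic-cohort generator with planted effects makes every
stage testable without any external download.

## Expression normalization

Raw read-count matrices go through three stages, in this order:

1. **Median-of-ratios size factors.** The reference set is every gene with
   strictly positive counts in all cell lines; the size factor of a column is
   the median over reference genes of `count / geometric mean across columns`.
   Columns are divided by their factor. A zero-heavy matrix can empty the
   reference set, so the pipeline removes genes that are zero in more than
   half of the cell lines *before* computing factors (the stage order inside
   the pipeline is a design choice; the two published orders differ only for
   genes near the 50%-zeros boundary).
2. **Quantile normalization.** The value at rank *r* in each column is
   replaced by the mean of the *r*-th order statistics across columns. Ties
   receive the mean of the reference values over the positions the tie group
   spans. With ties this averaging means columns share the reference
   distribution only approximately; the exact column-multiset identity is
   guaranteed (and tested) on tie-free data.
3. **Scaling.** Each column is multiplied by `1000 / mean` so every cell
   line's mean expression is 1000 (relative tolerance 1e-9).

Pre-normalized matrices (e.g. RMA microarray summaries) receive stage 3 only.
Missing values are rejected at ingestion rather than imputed; duplicate gene
rows are an error at read time and are only merged by the HGNC symbol mapper,
which keeps the higher-mean row on collision (deterministic, and favoring the
expressed probe) while reporting every collision and unmapped id.

## Response classification

For one compound in one dataset, response values (lower = more sensitive, for
both IC50 and AUDRC) are cut at the 33.33rd and 66.67th percentiles, computed
by linear interpolation between order statistics (the "type 7" convention —
chosen because it is the default of mainstream numeric stacks and
deterministic; the classification itself is rank-based, so labels are
invariant under any strictly increasing transform of the values). The lower
tertile is *sensitive*, the upper *resistant*, the middle excluded. When the
two cutoffs coincide (degenerate distributions) a value satisfying both
conditions is excluded, preventing contradictory labels. A median-based
scheme (strictly below / strictly above, ties excluded) is available as an
alternative. Classification needs at least 6 values (tertile) or 4 (median)
so that downstream ROC statistics are defined with at least 2 lines per
class. Duplicate measurements for one cell line are averaged beforehand; when
both metrics are present the preferred one (AUDRC by default) is used if at
least 6 lines report it, else the other.

## Single-gene statistics

The biomarker screen treats the resistant class as positive and expression as
score. The raw ROC AUC then equals `U / (n_s * n_r)`, where U is the midrank
Mann-Whitney statistic of the resistant group — the two tests are equivalent,
which is also the reason the AUC's p-value is defined as the two-sided
Mann-Whitney p rather than a separate AUC test. The reported AUC is folded to
`[0.5, 1]` with an explicit direction flag (`higher_in_resistant` /
`higher_in_sensitive` / `none`), because a gene whose *high* expression marks
*sensitivity* is as much a biomarker as its mirror image. The Mann-Whitney
p-value is exact when both groups have at most 20 observations and no ties,
otherwise a normal approximation with tie and continuity corrections is used.
Numerically, the AUC is stored together with U, so the identity
`raw_auc * n_s * n_r = U` holds by construction and tests assert it on the U
scale (exact) rather than through the rounded product.

Spearman correlation against the continuous response is computed over *all*
cell lines with both measurements, not the labeled subset, with midranks and
a two-sided t approximation. Multiple testing across exactly the gene set
screened in one call is adjusted by Benjamini-Hochberg (no cross-compound
pooling); a floating-point guard enforces the exact-math invariant q ≥ p.
Multi-gene analysis by mean expression of a set is available via
`mean_signature()`; the correlation-matrix report retains genes that are both
significant (p < 0.05) and correlated with the continuous response
(|rho| ≥ 0.20 by default).

## The random-forest signature

`run_signature_pipeline()` composes four deterministic stages from one seed:

1. stratified split into 66% training / 34% test (`round(0.66 n)` overall,
   per-class counts by largest remainder so the total is exact);
2. selection of candidate genes with two-sided Mann-Whitney p < 0.05 computed
   on *training* lines only — permuting test-set labels provably cannot
   change the selection, and a dedicated leakage-guard test enforces this;
3. a random-forest classifier on the selected genes' training expression.
   No suitable forest implementation is part of the package's allowed
   dependency set, so the forest is implemented natively (C++ via Rcpp):
   CART trees with Gini impurity, one bootstrap sample per tree, 500 trees,
   `floor(sqrt(p))` candidate features per split, trees grown to purity, and
   per-tree majority votes averaged into a probability. All draws come from
   R's RNG, so `set.seed` upstream makes fits reproducible;
4. evaluation on the held-out lines: predictions at probability threshold
   0.5 (a vote fraction ≥ 0.5 is called resistant) give the confusion matrix
   and accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
   specificity = TN/(TN+FP), precision = TP/(TP+FP), each reported as absent
   when its denominator is 0. The test AUC uses the predicted resistant
   probability as score and is *not* folded — the model fixes orientation —
   and its p-value is again the Mann-Whitney p of the probabilities.

The per-gene AUCs emitted for radar charts are full-cohort folded AUCs of the
selected genes, labeled as such.

## The synthetic cohort generator

The generator states a world with the statistical structure the pipeline
assumes and nothing more:

- a latent resistance score `z ~ N(0, 1)` per cell line, shared across
  datasets;
- raw counts that are log-normal around a per-gene baseline
  (log-mean ~ N(log 300, 1)) with per-entry log-noise SD fixed at 1, so a
  planted `effect_size` — the log-scale shift per SD of `z` — reads directly
  in pooled-SD units;
- dose response through a Hill curve `v(d) = 1 / (1 + (d / IC50)^h)` with
  `log IC50 = z + N(0, noise_sd)` and AUDRC as the trapezoid area over a
  geometric dose ladder on the log10 axis (default 1e-3 to 10, 9 points);
  recorded IC50 and AUDRC carry independent noise draws, and recorded AUDRC
  is standardized to the mean viability fraction in [0, 1];
- multi-dataset cohorts share a configurable core of overlapping cell lines,
  with dataset-specific measurement noise on shared lines.

Defaults (`noise_sd = 0.1`, 9-point ladder, effects quoted in SD) mirror what
low-noise, well-replicated screens look like after curve fitting. The
generator does **not** mimic real cohorts' marginal distributions, batch
structure, mutation effects, or missingness patterns — a green test
establishes that the statistics and pipeline logic are correct under the
stated model, not that any biological claim holds. The signature-superiority
check plants five additive markers at 1 pooled-SD each: a deliberately
moderate effect, strong enough to be selected yet weak enough that
aggregating correlated markers measurably beats the best single gene.

## Cell-line ranking and overlaps

"Standardized AUDRC" is defined as the raw area divided by its theoretical
maximum (dose-range width × maximal response), i.e. the mean response over
the tested range — a definition chosen for its [0, 1] scale and linearity
(it cannot reorder a shared-dose-range ranking). Ranking ties break by
cell-line name for determinism. Cross-dataset overlap reports enumerate all
exclusive Venn regions for 2-4 datasets plus "in at least two" / "in all"
aggregates with percentages of the union.

## Numerical and degenerate-input choices

- Tertile cutoffs landing on data values (possible with ties) keep the
  boundary value in the adjacent class via the `<=` / `>=` rules; fully
  degenerate inputs (all values equal) label everything excluded.
- `bh_fdr` clamps q to `max(q, p)` to keep the step-up invariant under
  floating-point rounding; p-values are floored at the smallest positive
  double so they remain in (0, 1].
- The stratified splitter errors (rather than silently proceeding) when any
  class would have fewer than 2 members in either partition.
- Normalization rejects all-zero cell lines by name instead of producing
  NaNs.

## Known limitations

- Only transcriptomic features are modeled; mutation status, copy number and
  tissue composition — all of which confound real screens — are out of scope.
- The engine consumes published IC50/AUDRC values; it does not fit
  dose-response curves from raw viability data (the Hill curve exists only
  inside the simulator).
- The forest has fixed, documented hyperparameters and no tuning or
  cross-validation; alternative classifiers are not provided.
- Tertile cutoffs are computed per dataset per compound; datasets are never
  pooled before classification.
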