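---
title: "Replicate-anchored hierarchical normalization: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-anchored hierarchical normalization: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large LC-MS metabolomics cohorts are acquired over weeks, in batches that
fit an autosampler tray. Two families of technical variation accumulate:
within-batch signal drift (column fouling, source contamination, tuning
changes — each metabolite responds differently, and on top of slow trends
there are abrupt jumps on the timescale of a few runs), and between-batch
shifts (column changes, cleaning, re-calibration, operator effects). Both
can be far larger than the biological differences of interest.

The classical remedy re-injects one pooled QC mixture periodically and
divides or regresses everything against it. A single reference sample is a
fragile anchor over months: its aliquots degrade, and one sample cannot
represent the heterogeneity of the cohort. This package implements the
alternative strategy of *embedding sample replicates in the run order* and
using them to estimate and remove unwanted variation hierarchically.

## The replicate design

A batch is laid out as a `rows_per_batch` x `row_size` grid (default 8 x
11): each row holds 10 individual-sample slots plus one pooled QC, and the
batch opens with conditioning QC injections (default 3) that warm up the
instrument and are excluded from normalization. Two kinds of sample
replicates are embedded:

* **short replicates** — from the second row onward, one randomly chosen,
  not-yet-replicated individual from an earlier row is re-injected at a
  random position in the current row. The pair sits roughly 11 runs apart
  and measures short-timescale technical variation on *real samples*, not
  just the pooled mixture;
* **batch replicates** — each batch after the first opens with re-injections
  of (default) 5 randomly chosen non-short-replicated individuals from the
  previous batch, linking consecutive batches.

For the reference 15-batch geometry this yields 105 short-replicate pairs
(210 measurements) and 70 batch-replicated samples observed in 140
measurements. `generate_design()` draws all selections from a seeded
stream, so a design sheet is reproducible, and `write_design_csv()` exports
it for the liquid handler. An optional stratified mode forces the
batch-replicate selection to cover both halves of the previous batch,
guarding against the chance clustering of selected positions that purely
random choice occasionally produces.

## Within-batch drift correction

On log2 signals \(y_{ij}\) (metabolite \(i\), measurement \(j\)), a robust
smoother \(\hat y^{*}_{ij}\) of signal against run index is fitted per
metabolite and the series is re-anchored at the batch median
\(\tilde y_i\):

\[ \hat y_{ij} = y_{ij} + (\tilde y_i - \hat y^{*}_{ij}). \]

Four smoother variants are provided: loess or a robust linear model (rlm),
fitted either to every measurement in the batch or to the pooled QCs only
(in which case the fit is evaluated at each sample's run index, clamped to
the QC span at the batch edges). Loess uses local quadratic fitting with
tricube weights, span 0.75 and no robustness iterations; rlm runs at most
100 IRLS iterations. A pooled-QC *ratio* method (dividing each raw signal
by its bracketing pooled QC, earlier QC up to the interval midpoint) is
included as the classical baseline.

Constant signals are exact fixed points of the correction. One degenerate
input needs care: an exactly linear response makes the IRLS scale estimate
zero, where `MASS::rlm` is undefined; `smooth_adjust()` detects a
numerically zero least-squares residual scale and uses the OLS line, which
is the robust fit in that case.

## Replicate-anchored removal of unwanted variation

On the measurements-by-metabolites matrix the model is

\[ Z = X\beta + W\alpha + \varepsilon, \]

with \(Z\) the per-metabolite mean-centred data, \(X\) the unobserved
factors of interest, and \(W\alpha\) a \(k\)-dimensional unwanted component
(default \(k = 5\)). Because technical replicates share a row of \(X\),
variation *within* replicate groups is biology-free. The estimator follows
the replicate-anchored (RUV-III) scheme:

1. build the replicate indicator \(M\) (one column per distinct biological
   sample) and residualize: \(R_M Z\) removes replicate-group means;
2. \(\hat\alpha\) = top-\(k\) right singular directions of \(R_M Z\);
3. \(\hat W\) = regression of the negative-control columns of \(Z\) on the
   control columns of \(\hat\alpha\) (default controls: all metabolites);
4. return \(Z - \hat W \hat\alpha\), then restore the per-metabolite means.

\(k\) is capped at the replicate residual rank (measurements minus distinct
samples) and additionally at the numerical rank of the residual matrix,
with a warning — inverting a singular control Gram matrix would otherwise
poison the adjustment. A `k_policy = "error"` switch turns the cap into a
hard error.

**Which replicate groups anchor the fit?** Within a batch, the short
replicate pairs; at a between-batch merge, every replicate group with at
least two members in the union (cross-batch links plus any intra-batch
pairs). The pipeline default also treats the pooled QC repeats as one
replicate group. The pooled QC genuinely is one biological sample injected
throughout the study, and its repeats carry no subject-to-subject biology,
so they sharpen the unwanted-factor estimate considerably: in simulations,
anchoring on the 7 short pairs (or 5 cross links) alone leaves enough
residual batch structure for k-means to recover batches (ARI around 0.3),
while adding the QC group drives the ARI to noise level. The historical
concern about pooled QCs — that QC-*only* estimation over-fits unwanted
variation and strips biology — applies to using them as the *sole* anchor,
not as a supplement to sample replicates; `include_qc_replicates = FALSE`
restores sample-replicate-only anchoring at both levels.

## Hierarchical integration

Intra-batch-corrected batches are merged pairwise along a binary tree,
applying the adjustment above at every merge. Two schedules are provided:

* **balanced** (`_H`): neighbouring batches are paired, then neighbouring
  pairs, and so on — \(\lceil\log_2 n\rceil\) sequential rounds;
* **concatenating** (`_Hc`): batches are absorbed one at a time into the
  growing normalized set — \(n-1\) rounds, but appending \(m\) new batches
  later costs only \(m\) further adjustments.

Both perform exactly \(n-1\) pairwise merges (any binary tree over \(n\)
leaves has \(n-1\) internal nodes); they differ in depth, not in work. With
an odd number of groups in a balanced layer the last group is carried
upward unmerged. Method tags compose the full pipeline, e.g.
`loessAllShort_batch_Hc` = loess on all samples, then short-replicate RUV
within each batch, then concatenating-tree RUV across batches.

## Evaluation battery

* within-replicate-group standard deviations (sample SD, groups of two or
  more), summarized by their median;
* per-sample skewness \(m_3/s^3\) (third central moment over the cubed
  sample SD);
* batch-clustering adjusted Rand index: k-means and complete-linkage
  hierarchical clustering with as many clusters as batches, compared with
  the batch labels through the pair-count form
  \(2(ad-bc)/[(a+b)(b+d)+(a+c)(c+d)]\) — low values mean the batch
  signature has dissolved. The linkage and the k-means restart count
  (20) are fixed in the defaults; k-means uses the caller's RNG stream;
* relative log expression (deviation from the per-metabolite median) and
  the data behind run plots and centred, unscaled PCA.

## The simulator and what passing tests mean

`simulate_experiment()` generates the full design with known ground truth:

\[ y = \text{baseline}_m + \text{subject}_m(s) + \text{effect}_m\,
   \text{phenotype}(s) + \Lambda_m^\top g_b(t) + \Lambda_m^\top u_b +
   \text{noise}. \]

Unwanted variation is *factor-structured*: a small number (default 5,
matching the default \(k\)) of latent instrument factors act on every
metabolite through fixed loadings \(\Lambda\). Each factor contributes a
slow within-batch trend \(g_b(t)\) (linear, or a sinusoid of at most one
cycle per batch plus a centred quadratic — the timescale of fouling and
tuning drift), a short-timescale irregular fluctuation (a moving-average
process with an ~8-run correlation length: invisible to a span-0.75
smoother, but caught by replicate pairs ~11 runs apart), and a per-batch
offset \(u_b\). Replicate measurements repeat their sample's biology but
receive the drift, offset and noise of their own run positions; the pooled
QC carries baseline biology only.

Default magnitudes, chosen to mirror a targeted plasma panel: 100
metabolites; baseline log2 levels N(20, 2); between-subject SD 0.4
(~30% CV); drift scale 1.2 and rough-fluctuation scale 0.4 log2 per batch;
batch offsets SD 1.5 (run plots of multi-batch studies routinely show
jumps of one to two log2 units); phenotype prevalence 0.39 with 10% of
metabolites shifted by 0.4 log2 (one subject SD — a moderately strong
clinical association); technical noise SD 0.1 (~7% CV, typical of targeted
MRM). The test suite runs the 6-batch default scenario end to end and
smaller 3-4-batch grids elsewhere; these sizes were chosen as the smallest
at which every phenomenon of interest (drift, batch clustering, replicate
agreement, merge trees of depth > 1) is expressed.

What the simulator does *not* emulate: peak integration artefacts,
retention-time shifts, censoring-type missingness (missing values are
injected completely at random), pooled-QC aliquot degradation over the
study, and heavy-tailed noise. Passing tests therefore demonstrate correct
mechanics and behaviour in the factor-structured regime, not performance
on every real-data pathology.

## Known limitations

* **Attenuation of concentrated biological modules.** Every RUV
  application removes the data's projection onto the \(k\) estimated
  factor directions. Directions beyond the genuine unwanted structure are
  noise-driven, and a smoother fitted through all samples anchors every
  measurement to a curve that partly tracks the local average of the
  biology, leaking a rank-one component of any strong group effect into
  the replicate residuals. Stacked over one intra-batch and up to
  \(n - 1\) merge applications, the default 6-batch pipeline retains
  roughly 60-75% of a phenotype effect concentrated on 10% of metabolites
  (the exact figure is seed-dependent; the acceptance suite computes it).
  Rank-based and cross-validated readouts (clustering, prediction) are
  unaffected by proportional shrinkage, but absolute effect sizes read off
  hRUV-normalized data are conservative. Smaller \(k\), fewer merge
  levels, or restricting controls reduce the attenuation at the cost of
  less complete batch-effect removal.
* The conditioning-QC outlier rule (median deviation from the pooled-QC
  profile, MAD-scaled, threshold 3.5) is a pragmatic choice; no
  field-standard criterion exists for these warm-up injections.
* The kNN imputer (sample-space neighbours, Euclidean distance over shared
  observed metabolites, distance-weighted mean, \(k = 10\)) assumes
  missingness unrelated to abundance; for intensity-dependent censoring a
  left-censored imputer would be more faithful. Imputed values can be
  masked back to missing after normalization (`restore_missing`).
* Presence filtering is evaluated once over the pooled study, not per
  batch, so a metabolite quantified in only a few batches survives if its
  overall presence clears the threshold.
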