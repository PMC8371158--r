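# hruv

Replicate-aware experimental design and hierarchical removal of unwanted
variation for large multi-batch LC-MS metabolomics studies.

## The problem

Cohort-scale metabolomics runs for weeks across many instrument batches.
Signals drift within a batch (column fouling, tuning, source condition)
and jump between batches (cleaning, column changes, operators), often by
more than the biological differences under study. Classical correction
regresses everything against a periodically re-injected pooled QC mixture,
but one reference sample degrades over months and cannot represent cohort
heterogeneity.

`hruv` implements the alternative: *embed biological sample replicates in
the run order* — a duplicate of an individual sample in each tray row
("short replicates", ~11 runs apart) and re-injections of five samples
from each batch at the start of the next ("batch replicates") — and use
them to estimate and subtract unwanted variation hierarchically.

## The model

Per metabolite, within-batch drift is removed by re-anchoring a robust
smoother (loess or rlm of log2 signal against run index, fitted to all
samples or to pooled QCs) at the batch median:

    y_adj = y + (median(y) - fitted(run)).

Across measurements, on the mean-centred measurements x metabolites matrix
Z, unwanted variation follows the factor model

    Z = X beta + W alpha + epsilon,

with k unwanted dimensions (default 5). Technical replicates share rows of
X, so loadings `alpha` are estimated from the top-k right singular
directions of the replicate-residualized matrix R_M Z, scores `W` by
regressing the negative-control columns of Z (default: all metabolites) on
the control columns of `alpha`, and `W alpha` is subtracted (the RUV-III
scheme). Batches are merged pairwise along a balanced tree (`_H`, depth
~log2 n) or a concatenating chain (`_Hc`, easy to extend with new
batches); both perform n - 1 merges, each one a replicate-anchored
adjustment linked by the batch replicates.

An evaluation battery quantifies the result: within-replicate-group
standard deviations, per-sample skewness (m3 / s^3), batch-clustering
adjusted Rand index (k-means and hierarchical; low = batch signature
gone), relative log expression, run-plot and PCA coordinates. A
ground-truth simulator generates complete multi-batch experiments with
factor-structured drift, batch shifts, subject-level biology and a planted
phenotype effect, so every stage can be benchmarked against truth.

## Worked example

```r
library(hruv)

# 1. plan a 15-batch study in the 8 x 11 replicate layout
design <- generate_design(design_config(n_batches = 15, seed = 1))
summarize_design(design)
#> Design summary
#>   batches: 15, total runs: 1365
#>   individuals: 1025 measurements of 1025 distinct samples
#>   pooled QC: 120 runs (+45 conditioning)
#>   short replicates: 105 pairs (210 measurements)
#>   batch replicates: 70 pairs (140 measurements, 70 distinct samples)

# 2. simulate a 6-batch study with known ground truth and normalize it
sim <- simulate_experiment(sim_config(seed = 1))
set.seed(1)                      # k-means in the evaluation
fit <- hruv(sim$batches)         # method = "loessAllShort_batch_Hc"
summary(fit)
#> hruv fit: method 'loessAllShort_batch_Hc'
#>   100 metabolites x 528 measurements in 6 batches
#>   merge tree: concatenating, 5 merges, depth 5
#>
#>   evaluation (before -> after adjustment):
#>     median replicate SD: 0.4252 -> 0.0491
#>     batch ARI (kmeans): 0.652 -> 0.003
#>     batch ARI (hclust): 0.645 -> 0.001

# 3. compare with the simulator's truth
truth_metrics(fit$assay, sim$truth)
#> Ground-truth recovery
#>   RMSE vs clean signal: 0.2069
#>   mean |cor(residual, run)|: 0.166
#>   median residual batch-offset SD: 0.0387
#>   recovered effect: mean 0.240 (true 0.40)
```

Reading the numbers: replicate injections that disagreed by a median SD of
0.43 log2 units in the raw data agree to 0.05 after normalization; k-means
can no longer recover the batch labels (ARI 0.65 to 0.003); residual
per-batch offsets shrink to 0.04 log2. The recovered phenotype effect
(0.24 of a planted 0.40 log2 shift) illustrates the attenuation that
stacked factor removal imposes on concentrated biological modules — see
the methods vignette (`vignettes/hruv-methods.Rmd`) for the mechanism and
its practical implications.

Diagnostics: `plot(fit, "run", metabolite = "met001")`,
`plot(fit, "rle")`, `plot(fit, "pca")`.

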