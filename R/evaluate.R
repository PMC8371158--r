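# Quantitative assessment of a normalization: replicate standard
# deviations, per-sample skewness, batch-clustering adjusted Rand index,
# relative log expression, and the data behind run and PCA diagnostic
# plots. All operations return plain tables; plotting is a thin optional
# layer on top.

#' Within-replicate-group standard deviations
#'
#' For every replicate group with at least two members, the sample standard
#' deviation (n - 1 denominator) of each metabolite across the group's
#' measurements. Low values indicate that technical replicates are close to
#' identical, i.e. successful removal of unwanted variation.
#'
#' @param x An `hruv_assay`.
#' @param map Optional [build_replicate_matrix()] result; by default every
#'   multi-member replicate group in the annotation (including pooled QC
#'   repeats) is used.
#' @return Data frame with columns `group`, `metabolite`, `n`, `sd`.
#' @export
replicate_sd <- function(x, map = NULL) {
  assert_assay(x)
  if (is.null(map)) map <- build_replicate_matrix(x)
  sizes <- colSums(map$indicator)
  groups <- which(sizes >= 2)
  if (!length(groups))
    stopf("no replicate group with >= 2 members")
  v <- x$values
  out <- lapply(groups, function(g) {
    idx <- which(map$indicator[, g] == 1)
    data.frame(group = map$group_ids[g],
               metabolite = rownames(v),
               n = length(idx),
               sd = apply(v[, idx, drop = FALSE], 1L, stats::sd, na.rm = TRUE),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Sample skewness
#'
#' Third central moment over the cubed sample standard deviation,
#' `m3 / s^3`, with `m3 = sum((x - mean)^3) / n` and `s` the usual (n - 1)
#' sample standard deviation. Needs at least three non-missing values;
#' returns `NA` for degenerate (zero-variance) input.
#'
#' @param x Numeric vector (missing values dropped).
#' @return Scalar skewness, or `NA` if undefined.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stopf("skewness needs at least 3 non-missing values")
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  mean((x - mean(x))^3) / s^3
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement, computed from the four pair
#' counts (together in both partitions, together in only one, together in
#' only the other, separated in both) as `2(ad - bc) / ((a+b)(b+d) +
#' (a+c)(c+d))`. Symmetric in its arguments; 1 for identical partitions and
#' about 0 for independent ones.
#'
#' @param a,b Partition label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("partitions must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  pairs <- function(x) sum(choose(x, 2))
  A <- pairs(tab)                       # together in both
  B <- pairs(rowSums(tab)) - A          # together in a only
  C <- pairs(colSums(tab)) - A          # together in b only
  D <- choose(n, 2) - A - B - C         # apart in both
  den <- (A + B) * (B + D) + (A + C) * (C + D)
  if (den == 0) return(1)               # both partitions all-singleton or all-one
  2 * (A * D - B * C) / den
}

#' Batch-clustering ARI
#'
#' Clusters measurements on all metabolites (k-means or hierarchical with
#' complete linkage) into as many clusters as there are batches, and
#' returns the ARI between cluster assignment and batch labels. Low values
#' indicate that batch structure no longer dominates the data.
#'
#' @param x An `hruv_assay` without missing entries (impute first).
#' @param method `"kmeans"` (default) or `"hierarchical"`.
#' @param n_clusters Number of clusters; defaults to the number of batches.
#' @param nstart Random restarts for k-means (default 20). Seed the RNG for
#'   reproducible k-means results.
#' @return Scalar ARI.
#' @export
batch_ari <- function(x, method = c("kmeans", "hierarchical"),
                      n_clusters = NULL, nstart = 20) {
  assert_assay(x)
  method <- match.arg(method)
  labels <- x$annotation$batch
  if (length(unique(labels)) < 2) stopf("need at least 2 batches")
  n_clusters <- n_clusters %||% length(unique(labels))
  v <- x$values
  X <- t(v)
  if (anyNA(X)) {
    keep <- !apply(X, 2L, anyNA)
    if (!any(keep)) stopf("every metabolite has missing values; impute first")
    X <- X[, keep, drop = FALSE]
  }
  cl <- if (method == "kmeans") {
    stats::kmeans(X, centers = n_clusters, nstart = nstart,
                  iter.max = 50)$cluster
  } else {
    stats::cutree(stats::hclust(stats::dist(X), method = "complete"),
                  k = n_clusters)
  }
  adjusted_rand_index(cl, labels)
}

#' Relative log expression
#'
#' Per-entry deviation of the log2 signal from its metabolite's median
#' across all measurements: the per-metabolite median of the result is 0,
#' and sample-wise boxplots of it should be tight around zero when unwanted
#' variation has been removed.
#'
#' @param x An `hruv_assay` on the log2 scale.
#' @return Matrix of the same dimensions as the assay values.
#' @export
rle_values <- function(x) {
  assert_assay(x)
  if (x$scale != "log2") stopf("rle_values expects a log2-scale assay")
  v <- x$values
  sweep(v, 1L, row_medians(v), `-`)
}

#' Run series for one metabolite
#'
#' @param x An `hruv_assay`.
#' @param metabolite Metabolite id.
#' @return Data frame `(run_index, value, batch)` sorted by run index — the
#'   data behind a run plot, which should be a flat horizontal band when no
#'   drift remains.
#' @export
run_series <- function(x, metabolite) {
  assert_assay(x)
  i <- match(metabolite, rownames(x$values))
  if (is.na(i)) stopf("unknown metabolite '%s'", metabolite)
  v <- x$values[i, ]
  o <- order(x$annotation$run_index)
  data.frame(run_index = x$annotation$run_index[o], value = v[o],
             batch = x$annotation$batch[o], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' First two principal-component scores
#'
#' PCA over all metabolites, centred but not scaled.
#'
#' @param x An `hruv_assay` without missing entries.
#' @return Matrix (measurements x 2) of PC1/PC2 scores, with the
#'   per-component standard deviations in `attr(, "sdev")`.
#' @export
pca_scores <- function(x) {
  assert_assay(x)
  v <- x$values
  X <- t(v)
  if (anyNA(X)) {
    keep <- !apply(X, 2L, anyNA)
    X <- X[, keep, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  scores <- p$x[, seq_len(k), drop = FALSE]
  if (k < 2L) scores <- cbind(scores, PC2 = 0)
  attr(scores, "sdev") <- p$sdev
  scores
}

#' Evaluation report
#'
#' Runs the full assessment battery on an assay: replicate SDs, per-sample
#' skewness, batch ARI under both clustering methods, RLE values and PCA
#' scores.
#'
#' @param x An `hruv_assay` (log2 scale, no missing values for the
#'   clustering metrics).
#' @param nstart Random restarts for the k-means ARI.
#' @return An `eval_report` list.
#' @export
evaluate_assay <- function(x, nstart = 20) {
  assert_assay(x)
  rsd <- replicate_sd(x)
  v <- x$values
  skew <- apply(v, 2L, function(col) {
    col <- col[!is.na(col)]
    if (length(col) < 3 || stats::sd(col) == 0) NA_real_
    else sample_skewness(col)
  })
  multi_batch <- length(unique(x$annotation$batch)) >= 2
  out <- list(
    replicate_sd = rsd,
    median_replicate_sd = stats::median(rsd$sd, na.rm = TRUE),
    skewness = skew,
    batch_ari = if (multi_batch)
      c(kmeans = batch_ari(x, "kmeans", nstart = nstart),
        hierarchical = batch_ari(x, "hierarchical"))
    else c(kmeans = NA_real_, hierarchical = NA_real_),
    rle = rle_values(x),
    pca = pca_scores(x))
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report\n")
  cat(sprintf("  median replicate SD: %.4f\n", x$median_replicate_sd))
  cat(sprintf("  batch ARI: kmeans %.3f, hierarchical %.3f\n",
              x$batch_ari["kmeans"], x$batch_ari["hierarchical"]))
  cat(sprintf("  skewness: median %.3f (IQR %.3f)\n",
              stats::median(x$skewness, na.rm = TRUE),
              stats::IQR(x$skewness, na.rm = TRUE)))
  invisible(x)
}
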