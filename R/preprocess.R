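# Pre-processing: log2 transform, study-wide 50% presence filter,
# sample-space kNN imputation, conditioning-QC outlier screen, and the
# restore step that puts masked missing values back after normalization.

#' Log2-transform a raw assay
#'
#' @param x An `hruv_assay` on the raw scale; every observed value must be
#'   strictly positive (no silent clamping).
#' @return The assay with `values` replaced by base-2 logarithms and
#'   `scale = "log2"`; the missing mask is unchanged.
#' @export
log2_transform <- function(x) {
  assert_assay(x)
  if (x$scale != "raw") stopf("assay is already on the %s scale", x$scale)
  obs <- !is.na(x$values)
  bad <- which(obs & x$values <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("non-positive signal for metabolite '%s' in measurement '%s'",
          rownames(x$values)[bad[1, 1]], colnames(x$values)[bad[1, 2]])
  x$values <- log2(x$values)
  x$scale <- "log2"
  x
}

#' Filter metabolites by presence across the study
#'
#' Keeps metabolites observed (not missing) in at least `min_presence` of
#' all measurements, pooled across every supplied batch — the filter is
#' applied once over the whole study, not per batch. A proportion exactly
#' equal to the threshold is retained ("at least").
#'
#' @param x An `hruv_assay` or a list of them sharing one metabolite panel.
#' @param min_presence Minimum fraction of measurements in which a
#'   metabolite must be observed (default 0.5).
#' @return Object of the same shape as `x` with low-presence metabolites
#'   removed; the dropped metabolite ids are attached as
#'   `attr(, "dropped_metabolites")`.
#' @export
presence_filter <- function(x, min_presence = 0.5) {
  if (!is_fraction(min_presence)) stopf("min_presence must be in [0, 1]")
  xs <- if (is_assay(x)) list(x) else x
  lapply(xs, assert_assay)
  obs <- do.call(cbind, lapply(xs, function(a) !a$missing & !is.na(a$values)))
  keep <- rowMeans(obs) >= min_presence
  if (!any(keep)) warnf("presence filter removed every metabolite")
  dropped <- rownames(xs[[1]]$values)[!keep]
  out <- lapply(xs, select_metabolites, idx = keep)
  if (is_assay(x)) out <- out[[1]] else names(out) <- names(x)
  attr(out, "dropped_metabolites") <- dropped
  out
}

#' k-nearest-neighbour imputation of missing values
#'
#' Neighbours are measurements (samples): for each missing entry the `k`
#' closest samples by Euclidean distance over the metabolites observed in
#' both samples — restricted to samples where the target metabolite is
#' observed — contribute a distance-weighted mean (weights `1/(d + eps)`).
#' Observed entries are never altered and the missing mask is preserved so
#' [restore_missing()] can undo the fill after normalization.
#'
#' @param x An `hruv_assay` on the log2 scale.
#' @param k Number of neighbours (default 10).
#' @return The assay with all missing entries filled.
#' @export
knn_impute <- function(x, k = 10) {
  assert_assay(x)
  if (x$scale != "log2") stopf("knn_impute expects a log2-scale assay")
  if (!is_count(k, min = 1)) stopf("k must be a count >= 1")
  v <- x$values
  obs <- !is.na(v)
  if (any(rowSums(obs) == 0))
    stopf("metabolite '%s' has no observed values",
          rownames(v)[which(rowSums(obs) == 0)[1]])
  if (any(colSums(obs) == 0))
    stopf("measurement '%s' has no observed values",
          colnames(v)[which(colSums(obs) == 0)[1]])
  need <- which(colSums(!obs) > 0)
  for (j in need) {
    miss_i <- which(!obs[, j])
    # squared distances from sample j to every other sample over shared
    # observed metabolites, normalized by the number of shared metabolites
    shared <- obs & obs[, j]
    d2 <- colSums((v - v[, j])^2 * shared, na.rm = TRUE) / pmax(colSums(shared), 1)
    d2[j] <- Inf
    d2[colSums(shared) == 0] <- Inf
    for (i in miss_i) {
      cand <- which(obs[i, ] & is.finite(d2))
      if (!length(cand))
        stopf("no neighbour observes metabolite '%s' for measurement '%s'",
              rownames(v)[i], colnames(v)[j])
      nn <- cand[order(d2[cand])][seq_len(min(k, length(cand)))]
      w <- 1 / (sqrt(d2[nn]) + 1e-6)
      v[i, j] <- sum(w * v[i, nn]) / sum(w)
    }
  }
  x$values <- v
  x
}

#' Restore masked missing values after normalization
#'
#' Entries flagged in the assay's missing mask are reset to `NA`; all other
#' entries are untouched. Composed with [knn_impute()] this lets sparse
#' metabolites travel through normalization without committing to the
#' imputed values downstream.
#'
#' @param x An `hruv_assay` whose missing mask was carried through the
#'   pipeline.
#' @return The assay with missing entries set back to `NA`.
#' @export
restore_missing <- function(x) {
  assert_assay(x)
  if (!identical(dim(x$missing), dim(x$values)))
    stopf("missing mask shape does not match values")
  x$values[x$missing] <- NA
  x
}

#' Screen conditioning QCs for outliers
#'
#' The conditioning QC runs at the start of each batch are instrument
#' warm-up injections of the pooled QC mixture; outlying ones are dropped
#' before normalization. Each conditioning QC is summarized by its median
#' log-signal deviation from the batch's pooled-QC per-metabolite medians,
#' and flagged when the robust z-score of that summary (MAD-scaled against
#' the batch's pooled-QC runs) exceeds `z_threshold`.
#'
#' @param x An `hruv_assay` containing one batch (or several; screened per
#'   batch) with pooled and conditioning QCs annotated.
#' @param z_threshold Robust z cutoff (default 3.5); `Inf` disables removal.
#' @return The assay with flagged conditioning QCs removed; the removals are
#'   reported in `attr(, "removed_qc")` (measurement id, batch, z).
#' @export
qc_outlier_screen <- function(x, z_threshold = 3.5) {
  assert_assay(x)
  ann <- x$annotation
  removed <- data.frame(measurement_id = character(), batch = ann$batch[0],
                        z = numeric(), stringsAsFactors = FALSE)
  drop <- logical(nrow(ann))
  for (b in unique(ann$batch)) {
    in_b <- ann$batch == b
    pool_idx <- which(in_b & ann$sample_type == "pooledQC")
    cond_idx <- which(in_b & ann$sample_type == "conditioningQC")
    if (!length(cond_idx) || !length(pool_idx)) next
    ref <- row_medians(x$values[, pool_idx, drop = FALSE])
    stat <- function(j) stats::median(x$values[, j] - ref, na.rm = TRUE)
    pool_stat <- vapply(pool_idx, stat, numeric(1))
    centre <- stats::median(pool_stat)
    scale <- stats::mad(pool_stat)
    for (j in cond_idx) {
      dev <- stat(j) - centre
      z <- if (scale > 0) abs(dev) / scale else if (abs(dev) > 0) Inf else 0
      if (z > z_threshold) {
        drop[j] <- TRUE
        removed <- rbind(removed,
                         data.frame(measurement_id = ann$measurement_id[j],
                                    batch = b, z = z,
                                    stringsAsFactors = FALSE))
      }
    }
  }
  out <- if (any(drop)) select_measurements(x, !drop) else x
  attr(out, "removed_qc") <- removed
  out
}
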