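# End-to-end pipeline: preprocess -> per-batch drift correction (+ optional
# short-replicate RUV) -> hierarchical inter-batch RUV -> optional missing
# restore -> evaluation. hruv() is the single user-facing entry point and
# returns a classed fit object.

#' Pipeline control parameters
#'
#' Collects every tunable of the pipeline with defaults matching the
#' method's reference settings: 5 unwanted factors per RUV application,
#' loess span 0.75, at most 100 rlm iterations, 50% presence filter, k = 10
#' imputation neighbours, conditioning-QC outlier threshold 3.5.
#'
#' @param method Method tag (see [parse_method_tag()]); default
#'   `"loessAllShort_batch_Hc"`.
#' @param k Unwanted factors per RUV application (default 5).
#' @param k_policy `"cap"` (default) or `"error"` when `k` exceeds the
#'   replicate residual rank.
#' @param controls `"all"` (default), `"adaptive"`, or a character vector of
#'   negative-control metabolite ids.
#' @param n_controls Number of controls for adaptive selection.
#' @param min_presence Presence-filter threshold (default 0.5).
#' @param impute_k Imputation neighbours (default 10).
#' @param loess_span Loess span (default 0.75).
#' @param rlm_max_iter Maximum rlm iterations (default 100).
#' @param qc_outlier_z Conditioning-QC robust-z cutoff (default 3.5).
#' @param drop_conditioning Exclude conditioning QCs from normalization
#'   after the outlier screen (default `TRUE`).
#' @param include_qc_replicates Use pooled-QC repeats as a replicate group
#'   in RUV alongside the sample replicates (default `TRUE`: the pooled QC
#'   is one biological sample re-injected throughout the study, and its
#'   repeats carry no biology, which stabilizes the unwanted-factor
#'   estimates; set `FALSE` to anchor on sample replicates only).
#' @param replicate_policy Replicate scope at each merge: `"all"` (default)
#'   or `"cross_only"`.
#' @param restore_missing Put originally missing entries back to `NA` in the
#'   final matrix (default `FALSE`).
#' @param seed Seed for the (k-means) evaluation clustering (default 1).
#' @return An `hruv_control` list.
#' @export
hruv_control <- function(method = "loessAllShort_batch_Hc", k = 5,
                         k_policy = c("cap", "error"), controls = "all",
                         n_controls = NULL, min_presence = 0.5,
                         impute_k = 10, loess_span = 0.75,
                         rlm_max_iter = 100, qc_outlier_z = 3.5,
                         drop_conditioning = TRUE,
                         include_qc_replicates = TRUE,
                         replicate_policy = c("all", "cross_only"),
                         restore_missing = FALSE, seed = 1L) {
  parse_method_tag(method)   # validate early
  ctl <- list(method = method, k = k, k_policy = match.arg(k_policy),
              controls = controls, n_controls = n_controls,
              min_presence = min_presence, impute_k = impute_k,
              loess_span = loess_span, rlm_max_iter = rlm_max_iter,
              qc_outlier_z = qc_outlier_z,
              drop_conditioning = isTRUE(drop_conditioning),
              include_qc_replicates = isTRUE(include_qc_replicates),
              replicate_policy = match.arg(replicate_policy),
              restore_missing = isTRUE(restore_missing),
              seed = as.integer(seed))
  class(ctl) <- "hruv_control"
  ctl
}

#' Save / load pipeline control parameters
#'
#' Flat YAML round trip: `read_hruv_control(write_hruv_control(ctl, path))`
#' reproduces `ctl`.
#'
#' @param ctl An [hruv_control()].
#' @param path File path.
#' @return `write_hruv_control` returns `path` invisibly;
#'   `read_hruv_control` an `hruv_control`.
#' @export
write_hruv_control <- function(ctl, path) {
  if (!inherits(ctl, "hruv_control")) stopf("`ctl` must be an hruv_control")
  yaml::write_yaml(unclass(ctl), path)
  invisible(path)
}

#' @rdname write_hruv_control
#' @export
read_hruv_control <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(hruv_control, vals[!vapply(vals, is.null, logical(1))])
}

#' Hierarchical replicate-anchored normalization
#'
#' Runs the full pipeline on raw per-batch signal matrices: log2 transform
#' (or the pooled-QC ratio), study-wide presence filter, kNN imputation,
#' conditioning-QC screen, per-batch drift correction with optional
#' short-replicate RUV, and hierarchical inter-batch RUV along the balanced
#' or concatenating merge tree. The output is a single normalized matrix
#' covering every input measurement, plus an evaluation report comparing it
#' with the pre-adjustment data.
#'
#' @param batches A list of single-batch `hruv_assay` objects on the raw
#'   scale (e.g. from [read_signal_csv()] or [simulate_experiment()]), or
#'   one merged raw assay.
#' @param control An [hruv_control()]; individual fields can be overridden
#'   through `...`.
#' @param phenotype Named binary vector per individual sample id; required
#'   only for `controls = "adaptive"`.
#' @param evaluate Compute the evaluation report (default `TRUE`).
#' @param ... Overrides for `control` fields, e.g. `method = "rlm_batch_H"`.
#' @return An `hruv_fit` with elements `assay` (normalized `hruv_assay`),
#'   `pre` (the assay after preprocessing, before any adjustment), `plan`,
#'   `merge_log`, `control`, `evaluation` (`pre`/`post` [evaluate_assay()]
#'   reports) and `dropped_metabolites`.
#' @export
hruv <- function(batches, control = hruv_control(), phenotype = NULL,
                 evaluate = TRUE, ...) {
  dots <- list(...)
  if (length(dots)) {
    vals <- utils::modifyList(unclass(control), dots)
    control <- do.call(hruv_control, vals)
  }
  if (is_assay(batches)) batches <- split_batches(batches)
  if (!length(batches)) stopf("no batches supplied")
  lapply(batches, assert_assay)
  spec <- parse_method_tag(control$method)

  stage <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", label, conditionMessage(e)))
  }

  # -- preprocessing ---------------------------------------------------
  # the outlier screen works on log2 signals; apply it to a transformed
  # copy and subset the raw batch accordingly
  batches <- stage("qc_screen", lapply(batches, function(b) {
    scr <- qc_outlier_screen(if (b$scale == "raw") log2_transform(b) else b,
                             z_threshold = control$qc_outlier_z)
    select_measurements(b, scr$annotation$measurement_id)
  }))
  if (control$drop_conditioning)
    batches <- lapply(batches, function(b)
      select_measurements(b, b$annotation$sample_type != "conditioningQC"))

  if (identical(spec$kind, "ratio")) {
    batches <- stage("ratio", lapply(batches, ratio_adjust))
  }
  batches <- stage("log2", lapply(batches, log2_transform))
  filtered <- stage("presence_filter",
                    presence_filter(batches, control$min_presence))
  dropped <- attr(filtered, "dropped_metabolites")
  batches <- filtered
  pooled <- bind_assays(batches)
  if (anyNA(pooled$values))
    pooled <- stage("impute", knn_impute(pooled, k = control$impute_k))
  batches <- split_batches(pooled)
  pre <- pooled

  # -- negative controls ----------------------------------------------
  controls <- NULL
  if (identical(control$controls, "adaptive")) {
    if (is.null(phenotype))
      stopf("[controls] adaptive selection needs a `phenotype` vector")
    nctl <- control$n_controls %||% ceiling(0.8 * nrow(pooled$values))
    controls <- stage("controls",
                      select_negative_controls(batches, phenotype, nctl))
  } else if (is.character(control$controls) &&
             !identical(control$controls, "all")) {
    controls <- control$controls
  }

  # -- intra-batch adjustment ------------------------------------------
  if (!identical(spec$kind, "ratio")) {
    batches <- stage("intrabatch", lapply(batches, function(b) {
      out <- smooth_adjust(b, smoother_spec(spec$kind, spec$smoother$scope,
                                            span = control$loess_span,
                                            max_iterations = control$rlm_max_iter))
      if (spec$short)
        out <- ruv_short(out, k = control$k, controls = controls,
                         include_qc = control$include_qc_replicates,
                         k_policy = control$k_policy)
      out
    }))
  }

  # -- hierarchical inter-batch adjustment -----------------------------
  plan <- NULL; merge_log <- data.frame()
  if (!is.null(spec$strategy) && length(batches) > 1) {
    plan <- stage("plan", switch(spec$strategy,
                                 balanced = balanced_plan(names(batches)),
                                 concatenating = concat_plan(names(batches))))
    res <- stage("merge", execute_plan(batches, plan, k = control$k,
                                       controls = controls,
                                       replicate_policy = control$replicate_policy,
                                       include_qc = control$include_qc_replicates,
                                       k_policy = control$k_policy))
    final <- res$assay
    merge_log <- res$log
  } else {
    final <- bind_assays(batches)
  }
  # restore acquisition order
  final <- select_measurements(final, order(final$annotation$run_index))

  evaluation <- NULL
  if (evaluate) {
    evaluation <- stage("evaluate", with_seed(control$seed, list(
      pre = evaluate_assay(pre),
      post = evaluate_assay(final))))
  }
  if (control$restore_missing) final <- restore_missing(final)

  structure(list(assay = final, pre = pre, plan = plan,
                 merge_log = merge_log, control = control,
                 controls_used = controls, evaluation = evaluation,
                 dropped_metabolites = dropped),
            class = "hruv_fit")
}

#' @export
print.hruv_fit <- function(x, ...) {
  a <- x$assay
  cat(sprintf("hruv fit: method '%s'\n", x$control$method))
  cat(sprintf("  %d metabolites x %d measurements in %d batches\n",
              nrow(a$values), ncol(a$values),
              length(unique(a$annotation$batch))))
  if (!is.null(x$plan))
    cat(sprintf("  merge tree: %s, %d merges, depth %d\n",
                x$plan$strategy, x$plan$n_merges, x$plan$depth))
  if (length(x$dropped_metabolites))
    cat(sprintf("  dropped by presence filter: %d metabolites\n",
                length(x$dropped_metabolites)))
  invisible(x)
}

#' @export
summary.hruv_fit <- function(object, ...) {
  out <- list(fit = object)
  class(out) <- "summary.hruv_fit"
  out
}

#' @export
print.summary.hruv_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$evaluation)) {
    pre <- f$evaluation$pre; post <- f$evaluation$post
    cat("\n  evaluation (before -> after adjustment):\n")
    cat(sprintf("    median replicate SD: %.4f -> %.4f\n",
                pre$median_replicate_sd, post$median_replicate_sd))
    cat(sprintf("    batch ARI (kmeans): %.3f -> %.3f\n",
                pre$batch_ari["kmeans"], post$batch_ari["kmeans"]))
    cat(sprintf("    batch ARI (hclust): %.3f -> %.3f\n",
                pre$batch_ari["hierarchical"], post$batch_ari["hierarchical"]))
  }
  if (nrow(f$merge_log)) {
    cat("\n  merges:\n")
    for (i in seq_len(nrow(f$merge_log)))
      cat(sprintf("    layer %d: {%s} + {%s} (k = %d)\n",
                  f$merge_log$layer[i], f$merge_log$left[i],
                  f$merge_log$right[i], f$merge_log$k_used[i]))
  }
  invisible(x)
}

#' Diagnostic plots for a fit
#'
#' `type = "run"`: signal of one metabolite against global run order,
#' before and after normalization; `"rle"`: per-sample relative log
#' expression boxplots; `"pca"`: first two principal components coloured by
#' batch.
#'
#' @param x An `hruv_fit`.
#' @param type `"run"`, `"rle"` or `"pca"`.
#' @param metabolite Metabolite id for the run plot (default: first).
#' @param ... Unused.
#' @return The fit, invisibly (called for the plot side effect).
#' @export
plot.hruv_fit <- function(x, type = c("run", "rle", "pca"),
                          metabolite = NULL, ...) {
  type <- match.arg(type)
  a <- x$assay
  batch <- factor(a$annotation$batch)
  if (type == "run") {
    metabolite <- metabolite %||% rownames(a$values)[1]
    old <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 2, 1))
    on.exit(graphics::par(old))
    for (obj in list(before = x$pre, after = a)) {
      s <- run_series(obj, metabolite)
      graphics::plot(s$run_index, s$value, col = as.integer(factor(s$batch)),
                     pch = 16, cex = 0.6, xlab = "run", ylab = "log2 signal",
                     main = sprintf("%s", metabolite))
    }
  } else if (type == "rle") {
    graphics::boxplot(rle_values(a), outline = FALSE, col = batch,
                      names = NULL, xaxt = "n", ylab = "RLE")
    graphics::abline(h = 0, lty = 2)
  } else {
    sc <- pca_scores(a)
    graphics::plot(sc[, 1], sc[, 2], col = as.integer(batch), pch = 16,
                   xlab = "PC1", ylab = "PC2")
  }
  invisible(x)
}

#' Final normalized matrix of a fit
#'
#' @param x An `hruv_fit`.
#' @return Numeric matrix, metabolites x measurements (log2 scale).
#' @export
normalized_values <- function(x) {
  if (!inherits(x, "hruv_fit")) stopf("`x` must be an hruv_fit")
  x$assay$values
}
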