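# Within-batch signal-drift correction. Each metabolite is detrended
# separately: either by the classical pooled-QC ratio, or by a robust
# smoother (loess or a robust linear model) of signal against run index,
# fitted on all samples or on pooled QCs only, re-centred at the
# metabolite's batch median:
#
#   y_adj = y + (median(y) - fitted(run))
#
# Optionally followed by RUV anchored on the batch's short replicates.

#' Smoother specification for drift correction
#'
#' @param kind `"loess"` (local quadratic regression, tricube weights, no
#'   robustness iterations) or `"rlm"` (M-estimated linear model).
#' @param scope Fit on `"all_samples"` (every measurement in the batch) or
#'   `"pooled_qc"` (pooled QC runs only; fitted values are evaluated at each
#'   sample's run index, clamped to the QC span at the batch edges).
#' @param span Loess span (default 0.75).
#' @param max_iterations Maximum IRLS iterations for `rlm` (default 100).
#' @return A `smoother_spec` list.
#' @export
smoother_spec <- function(kind = c("loess", "rlm"),
                          scope = c("all_samples", "pooled_qc"),
                          span = 0.75, max_iterations = 100) {
  kind <- match.arg(kind); scope <- match.arg(scope)
  if (!is.numeric(span) || span <= 0 || span > 1)
    stopf("span must be in (0, 1]")
  if (!is_count(max_iterations, min = 1))
    stopf("max_iterations must be a count >= 1")
  structure(list(kind = kind, scope = scope, span = span,
                 max_iterations = max_iterations),
            class = "smoother_spec")
}

#' Pooled-QC ratio adjustment
#'
#' Divides every raw signal by its bracketing pooled-QC signal: runs in the
#' first half of a QC-to-QC interval use the earlier QC, runs in the second
#' half the later one (a run at the midpoint uses the earlier QC; runs
#' before the first or after the last QC use the nearest one).
#'
#' @param x A single-batch `hruv_assay` on the raw scale with pooled QC runs
#'   annotated.
#' @return The assay of signal ratios (still `"raw"` scale; a pooled QC run
#'   maps to 1 for every metabolite).
#' @export
ratio_adjust <- function(x) {
  assert_assay(x)
  if (x$scale != "raw") stopf("ratio_adjust requires the raw scale")
  ann <- x$annotation
  qc <- which(ann$sample_type == "pooledQC")
  if (!length(qc)) stopf("no pooled QC runs in the batch")
  qc_runs <- ann$run_index[qc]
  o <- order(qc_runs); qc <- qc[o]; qc_runs <- qc_runs[o]
  # map each measurement to its bracketing QC column
  ref <- integer(nrow(ann))
  for (j in seq_len(nrow(ann))) {
    l <- ann$run_index[j]
    before <- which(qc_runs <= l)
    after <- which(qc_runs > l)
    if (!length(before)) ref[j] <- qc[after[1]]
    else if (!length(after)) ref[j] <- qc[before[length(before)]]
    else {
      L <- qc_runs[before[length(before)]]
      U <- qc_runs[after[1]]
      ref[j] <- if (l <= L + (U - L) / 2) qc[before[length(before)]]
      else qc[after[1]]
    }
  }
  P <- x$values[, ref, drop = FALSE]
  bad <- which(is.na(P) | P <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stopf("pooled QC signal missing or non-positive for metabolite '%s'",
          rownames(x$values)[bad[1, 1]])
  x$values <- x$values / P
  x
}

#' Smoother-based drift adjustment
#'
#' Fits, per metabolite, the specified smoother of log2 signal against run
#' index on the scope's measurements, then shifts every measurement by the
#' gap between the metabolite's batch median and its fitted value. Missing
#' entries are ignored during fitting and left missing.
#'
#' @param x A single-batch `hruv_assay` on the log2 scale.
#' @param spec A [smoother_spec()].
#' @return The drift-corrected assay.
#' @export
smooth_adjust <- function(x, spec = smoother_spec()) {
  assert_assay(x)
  if (x$scale != "log2") stopf("smooth_adjust expects a log2-scale assay")
  if (!inherits(spec, "smoother_spec")) stopf("`spec` must be a smoother_spec")
  ann <- x$annotation
  run <- ann$run_index
  scope <- if (spec$scope == "pooled_qc") ann$sample_type == "pooledQC"
  else rep(TRUE, nrow(ann))
  if (spec$scope == "pooled_qc" && !any(scope))
    stopf("no pooled QC runs to fit on")
  v <- x$values
  for (i in seq_len(nrow(v))) {
    y <- v[i, ]
    fit_idx <- which(scope & !is.na(y))
    if (length(fit_idx) < 4)
      stopf("metabolite '%s': only %d points in the fitting scope (need >= 4)",
            rownames(v)[i], length(fit_idx))
    pred <- fit_drift(run[fit_idx], y[fit_idx], run, spec, rownames(v)[i])
    med <- stats::median(y, na.rm = TRUE)
    v[i, ] <- y + (med - pred)
  }
  x$values <- v
  x
}

fit_drift <- function(run_fit, y_fit, run_all, spec, met) {
  if (spec$kind == "loess") {
    fit <- stats::loess(y_fit ~ run_fit, span = spec$span, degree = 2,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    # clamp evaluation to the fitted span (relevant for pooled-QC scope)
    run_eval <- pmin(pmax(run_all, min(run_fit)), max(run_fit))
    as.numeric(stats::predict(fit, newdata = data.frame(run_fit = run_eval)))
  } else {
    ls <- stats::lm.fit(cbind(1, run_fit), y_fit)
    if (stats::mad(ls$residuals) < 1e-10 * max(1, stats::mad(y_fit))) {
      # exactly (or numerically) linear response: the IRLS scale estimate is
      # zero and rlm is undefined; the LS line is already the robust fit
      co <- ls$coefficients
    } else {
      fit <- tryCatch(
        MASS::rlm(y_fit ~ run_fit, maxit = spec$max_iterations),
        error = function(e)
          stopf("metabolite '%s': rlm failed (%s)", met, conditionMessage(e)))
      if (!fit$converged)
        stopf("metabolite '%s': rlm did not converge within %d iterations",
              met, spec$max_iterations)
      co <- stats::coef(fit)
    }
    co[1] + co[2] * run_all
  }
}

#' RUV with short (intra-batch) replicates
#'
#' Applies the replicate-anchored adjustment ([adjust_group()]) within one
#' batch, using only the batch's short-replicate pairs as replicate groups
#' (pooled-QC repeats are excluded by default; every other measurement is
#' its own group).
#'
#' @param x A single-batch `hruv_assay` (log2 scale) containing at least one
#'   short-replicate pair.
#' @param k Number of unwanted factors (default 5); `k = 0` returns the
#'   input unchanged.
#' @param controls Negative-control metabolites (default all).
#' @param include_qc Also treat the batch's pooled QC runs as a replicate
#'   group (default `FALSE`).
#' @param k_policy Passed to [ruv3_adjust()].
#' @return The adjusted assay, same dimensions.
#' @export
ruv_short <- function(x, k = 5, controls = NULL, include_qc = FALSE,
                      k_policy = c("cap", "error")) {
  assert_assay(x)
  if (!is_count(k)) stopf("k must be a non-negative count")
  if (k == 0) return(x)
  labels <- replicate_labels(x$annotation, scope = "short",
                             include_qc = include_qc)
  if (attr(labels, "n_replicated") == 0)
    stopf("batch has no short-replicate pairs: skip the RUV step for it")
  map <- build_replicate_matrix(labels)
  x$values <- t(adjust_group(t(x$values), map, controls = controls, k = k,
                             k_policy = match.arg(k_policy)))
  x
}

# Collapse replicate_group labels to the groups RUV may use; everything
# else becomes a singleton. scope "short" keeps groups that contain a
# shortReplicate measurement; scope "all" keeps any multi-member group;
# scope "cross" keeps groups spanning more than one batch.
replicate_labels <- function(ann, scope = c("short", "all", "cross"),
                             include_qc = FALSE) {
  scope <- match.arg(scope)
  labels <- ann$replicate_group
  qc <- ann$sample_type %in% QC_TYPES
  keep_group <- function(g) {
    in_g <- labels == g
    if (sum(in_g) < 2) return(FALSE)
    if (scope == "short") any(ann$sample_type[in_g] == "shortReplicate")
    else if (scope == "cross") length(unique(ann$batch[in_g])) > 1
    else TRUE
  }
  if (include_qc && any(qc)) {
    qc_ok <- scope != "cross" || length(unique(ann$batch[qc])) > 1
  } else qc_ok <- FALSE
  out <- labels
  n_rep <- 0L
  for (g in unique(labels)) {
    is_qc_group <- any(qc[labels == g])
    ok <- if (is_qc_group) qc_ok && sum(labels == g) >= 2 else keep_group(g)
    if (ok) n_rep <- n_rep + 1L
    else {
      idx <- which(labels == g)
      out[idx] <- sprintf(".single_%s_%d", g, seq_along(idx))
    }
  }
  attr(out, "n_replicated") <- n_rep
  out
}

#' Run a tagged intra-batch normalization
#'
#' Applies the intra-batch part of a method tag: a smoother or the ratio
#' method, optionally followed by short-replicate RUV. Recognised tags
#' combine a smoother name (`loess`/`rlm` fit pooled QCs only;
#' `loessSample`/`rlmSample`/`loessAll`/`rlmAll` fit all samples), an
#' optional `Short` suffix for the RUV step, or `ratio`.
#'
#' @param x A single-batch `hruv_assay` (`"raw"` scale for `ratio`, log2
#'   otherwise).
#' @param method_tag Intra-batch tag, e.g. `"loessAllShort"`.
#' @param k,controls,include_qc,k_policy Passed to [ruv_short()].
#' @param span,max_iterations Passed to [smoother_spec()].
#' @return The normalized assay.
#' @export
run_intrabatch <- function(x, method_tag, k = 5, controls = NULL,
                           include_qc = FALSE, k_policy = "cap",
                           span = 0.75, max_iterations = 100) {
  spec <- parse_intrabatch_tag(method_tag, span = span,
                               max_iterations = max_iterations)
  if (identical(spec$kind, "ratio")) {
    if (spec$short) stopf("the ratio method has no short-replicate RUV variant")
    return(ratio_adjust(x))
  }
  out <- smooth_adjust(x, spec$smoother)
  if (spec$short)
    out <- ruv_short(out, k = k, controls = controls,
                     include_qc = include_qc, k_policy = k_policy)
  out
}

INTRABATCH_TAGS <- c("ratio", "loess", "rlm", "loessSample", "rlmSample",
                     "loessAll", "rlmAll")

parse_intrabatch_tag <- function(tag, span = 0.75, max_iterations = 100) {
  if (!is.character(tag) || length(tag) != 1)
    stopf("method tag must be a single string")
  short <- grepl("Short$", tag)
  base <- sub("Short$", "", tag)
  if (!base %in% INTRABATCH_TAGS)
    stopf("unknown intra-batch tag '%s'; valid tags: %s (each optionally followed by 'Short')",
          tag, paste(INTRABATCH_TAGS, collapse = ", "))
  if (base == "ratio")
    return(list(kind = "ratio", short = short, smoother = NULL))
  kind <- if (grepl("^loess", base)) "loess" else "rlm"
  scope <- if (base %in% c("loess", "rlm")) "pooled_qc" else "all_samples"
  list(kind = kind, short = short,
       smoother = smoother_spec(kind, scope, span = span,
                                max_iterations = max_iterations))
}
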