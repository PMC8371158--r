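# hruv_assay: the package's signal container. One object holds either a
# single acquisition batch or a merged set of batches; the annotation keeps
# the per-measurement design metadata (run order, grid position, sample type,
# replicate group) that every downstream stage consumes.

#' Recognised sample types
#'
#' `individual` biological samples, `pooledQC` (the pooled quality-control
#' mixture re-injected once per row), `conditioningQC` (the pooled-QC runs at
#' the start of a batch used to condition the instrument), `shortReplicate`
#' (a within-batch duplicate of an individual sample) and `batchReplicate`
#' (a re-injection in batch *b*+1 of a sample already run in batch *b*).
#'
#' @format Character vector of the five sample-type labels.
#' @export
SAMPLE_TYPES <- c("individual", "pooledQC", "conditioningQC",
                  "shortReplicate", "batchReplicate")

QC_TYPES <- c("pooledQC", "conditioningQC")

ANNOTATION_COLS <- c("measurement_id", "batch", "run_index", "row", "column",
                     "sample_id", "sample_type", "replicate_group")

measurement_id <- function(run_index) sprintf("r%05d", as.integer(run_index))

#' Construct a signal assay
#'
#' Bundles a metabolite-by-measurement signal matrix with its per-measurement
#' annotation. Missing values are carried as `NA` in `values` and tracked in
#' a logical mask so they can be restored after imputation and normalization.
#'
#' @param values Numeric matrix, metabolites in rows (rownames required),
#'   measurements in columns. Column names default to ids derived from the
#'   annotation's `run_index`.
#' @param annotation Data frame with one row per measurement and columns
#'   `batch`, `run_index`, `row`, `column`, `sample_id`, `sample_type`,
#'   `replicate_group` (a `measurement_id` column is added if absent).
#' @param scale Either `"raw"` (ion intensities) or `"log2"`.
#' @param missing Optional logical matrix marking missing entries; defaults
#'   to `is.na(values)`.
#' @return An object of class `hruv_assay`.
#' @export
hruv_assay <- function(values, annotation, scale = c("raw", "log2"),
                       missing = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stopf("`values` must have metabolite rownames")
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (!"measurement_id" %in% names(annotation))
    annotation$measurement_id <- measurement_id(annotation$run_index)
  need <- setdiff(ANNOTATION_COLS, names(annotation))
  if (length(need))
    stopf("annotation is missing column(s): %s", paste(need, collapse = ", "))
  annotation <- annotation[ANNOTATION_COLS]
  if (nrow(annotation) != ncol(values))
    stopf("annotation has %d rows but `values` has %d measurements",
          nrow(annotation), ncol(values))
  if (anyDuplicated(annotation$measurement_id))
    stopf("duplicated measurement ids in annotation")
  if (is.null(colnames(values))) {
    colnames(values) <- annotation$measurement_id
  } else if (!identical(colnames(values), annotation$measurement_id)) {
    if (!setequal(colnames(values), annotation$measurement_id))
      stopf("`values` column names do not match annotation measurement ids")
    annotation <- annotation[match(colnames(values),
                                   annotation$measurement_id), ]
  }
  bad <- setdiff(unique(annotation$sample_type), SAMPLE_TYPES)
  if (length(bad))
    stopf("unknown sample_type(s): %s", paste(bad, collapse = ", "))
  if (is.null(missing)) missing <- is.na(values)
  if (!is.logical(missing) || !identical(dim(missing), dim(values)))
    stopf("`missing` mask must be a logical matrix matching `values`")
  dimnames(missing) <- dimnames(values)
  rownames(annotation) <- NULL
  structure(list(values = values, annotation = annotation, scale = scale,
                 missing = missing),
            class = "hruv_assay")
}

is_assay <- function(x) inherits(x, "hruv_assay")

assert_assay <- function(x, arg = "x") {
  if (!is_assay(x)) stopf("`%s` must be an hruv_assay", arg)
  invisible(x)
}

#' @export
print.hruv_assay <- function(x, ...) {
  a <- x$annotation
  cat(sprintf("hruv_assay: %d metabolites x %d measurements (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  batches: %s\n", paste(unique(a$batch), collapse = ", ")))
  tab <- table(factor(a$sample_type, levels = SAMPLE_TYPES))
  cat("  sample types:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  nmiss <- sum(x$missing)
  if (nmiss > 0) cat(sprintf("  missing entries: %d\n", nmiss))
  invisible(x)
}

#' @export
dim.hruv_assay <- function(x) dim(x$values)

#' Subset an assay by measurement
#'
#' @param x An `hruv_assay`.
#' @param idx Logical, integer or character index over measurements.
#' @return The subsetted `hruv_assay`.
#' @keywords internal
select_measurements <- function(x, idx) {
  assert_assay(x)
  if (is.character(idx)) idx <- match(idx, x$annotation$measurement_id)
  hruv_assay(x$values[, idx, drop = FALSE],
             x$annotation[idx, , drop = FALSE],
             scale = x$scale,
             missing = x$missing[, idx, drop = FALSE])
}

select_metabolites <- function(x, idx) {
  assert_assay(x)
  hruv_assay(x$values[idx, , drop = FALSE],
             x$annotation,
             scale = x$scale,
             missing = x$missing[idx, , drop = FALSE])
}

#' Combine assays measurement-wise
#'
#' Binds the measurements of several assays (identical metabolite panels and
#' scale) into one assay, e.g. to pool batches before a merge-level
#' adjustment or a study-wide filter.
#'
#' @param ... `hruv_assay` objects, or a single list of them.
#' @return A single `hruv_assay`.
#' @export
bind_assays <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !is_assay(xs[[1]])) xs <- xs[[1]]
  if (!length(xs)) stopf("no assays supplied")
  lapply(xs, assert_assay)
  ref <- rownames(xs[[1]]$values)
  for (x in xs[-1]) {
    if (!identical(rownames(x$values), ref))
      stopf("assays have differing metabolite panels")
    if (!identical(x$scale, xs[[1]]$scale))
      stopf("assays are on different scales")
  }
  hruv_assay(do.call(cbind, lapply(xs, `[[`, "values")),
             do.call(rbind, lapply(xs, `[[`, "annotation")),
             scale = xs[[1]]$scale,
             missing = do.call(cbind, lapply(xs, `[[`, "missing")))
}

#' Split a merged assay into per-batch assays
#'
#' @param x An `hruv_assay`.
#' @return Named list of `hruv_assay` objects, one per batch, in order of
#'   first appearance.
#' @export
split_batches <- function(x) {
  assert_assay(x)
  ids <- unique(x$annotation$batch)
  out <- lapply(ids, function(b) select_measurements(x, x$annotation$batch == b))
  names(out) <- as.character(ids)
  out
}
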