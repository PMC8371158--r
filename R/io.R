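# Tabular I/O for signal matrices. Convention: first column the metabolite
# id, remaining columns one per measurement, headed by measurement ids that
# match the design sheet (derived from the global run index). Missing
# values are empty cells or NA.

#' Write / read a signal matrix as CSV
#'
#' @param x An `hruv_assay`.
#' @param path File path.
#' @param design A design sheet (or annotation data frame) supplying the
#'   per-measurement metadata for the file's measurement columns.
#' @param scale Scale to record on the assay read back (`"raw"` or
#'   `"log2"`).
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns an `hruv_assay`.
#' @export
write_signal_csv <- function(x, path) {
  assert_assay(x)
  v <- x$values
  v[x$missing] <- NA
  df <- data.frame(metabolite = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path, design, scale = c("raw", "log2")) {
  scale <- match.arg(scale)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("%s: expected a metabolite column plus measurements", path)
  mets <- as.character(df[[1]])
  if (anyDuplicated(mets))
    stopf("%s: duplicated metabolite id '%s'", path, mets[duplicated(mets)][1])
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- mets
  ann <- if (inherits(design, "design_sheet")) design_annotation(design)
  else as.data.frame(design)
  if (!"measurement_id" %in% names(ann))
    ann$measurement_id <- measurement_id(ann$run_index)
  idx <- match(colnames(v), ann$measurement_id)
  if (anyNA(idx))
    stopf("%s: measurement '%s' not found in the design",
          path, colnames(v)[which(is.na(idx))[1]])
  hruv_assay(v, ann[idx, , drop = FALSE], scale = scale)
}
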