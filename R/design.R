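# Replicate-embedding run-order design. A batch is laid out as a
# rows_per_batch x row_size autosampler grid: each row holds row_size - 1
# individual-type measurements followed by one pooled QC. Conditioning QCs
# (instrument fine-adjustment runs at the start of each batch) sit outside
# the grid and are recorded with row = 0. From the second row of every batch
# onward, one randomly chosen not-yet-replicated individual from an earlier
# row is re-injected at a random position ("short replicate"); each batch
# after the first opens with a contiguous block of re-injections of randomly
# chosen non-short-replicated individuals from the previous batch
# ("batch replicates").

#' Design configuration for a replicate-embedding experiment
#'
#' Defaults reproduce an 8 x 11 batch grid (10 individual slots + 1 pooled
#' QC per row), 5 inter-batch replicates per batch transition and 3
#' conditioning QC runs at the start of every batch.
#'
#' @param n_batches Number of batches (>= 1).
#' @param rows_per_batch Grid rows per batch (default 8).
#' @param row_size Measurements per row including the pooled QC (default 11).
#' @param n_batch_replicates Inter-batch replicates per transition (default 5).
#' @param n_conditioning_qc Pooled-QC conditioning runs at batch start
#'   (default 3).
#' @param short_replicate_source Where short-replicate sources may come from:
#'   `"any_earlier_row"` (default) or `"previous_row"` only.
#' @param stratify_batch_replicates If `TRUE`, batch-replicate selection is
#'   stratified across the two halves of the previous batch to avoid
#'   accidental clustering of the selected positions (default `FALSE`).
#' @param seed Integer seed for the random selections (default 1).
#' @return A `design_config` list.
#' @export
design_config <- function(n_batches,
                          rows_per_batch = 8,
                          row_size = 11,
                          n_batch_replicates = 5,
                          n_conditioning_qc = 3,
                          short_replicate_source = c("any_earlier_row",
                                                     "previous_row"),
                          stratify_batch_replicates = FALSE,
                          seed = 1L) {
  short_replicate_source <- match.arg(short_replicate_source)
  cfg <- list(n_batches = n_batches,
              rows_per_batch = rows_per_batch,
              row_size = row_size,
              n_batch_replicates = n_batch_replicates,
              n_conditioning_qc = n_conditioning_qc,
              short_replicate_source = short_replicate_source,
              stratify_batch_replicates = isTRUE(stratify_batch_replicates),
              seed = as.integer(seed))
  validate_design_config(cfg)
  class(cfg) <- "design_config"
  cfg
}

validate_design_config <- function(cfg) {
  if (!is_count(cfg$n_batches, min = 1)) stopf("n_batches must be a count >= 1")
  if (!is_count(cfg$rows_per_batch, min = 1))
    stopf("rows_per_batch must be a count >= 1")
  if (!is_count(cfg$row_size, min = 2))
    stopf("row_size must be >= 2 (at least one individual slot plus the pooled QC)")
  if (!is_count(cfg$n_batch_replicates)) stopf("n_batch_replicates must be a count")
  if (!is_count(cfg$n_conditioning_qc)) stopf("n_conditioning_qc must be a count")
  ind_slots <- (cfg$row_size - 1) * cfg$rows_per_batch
  if (cfg$n_batch_replicates >= ind_slots)
    stopf("n_batch_replicates (%d) must be smaller than the %d individual slots per batch",
          cfg$n_batch_replicates, ind_slots)
  if (cfg$n_batches > 1 && cfg$n_batch_replicates > cfg$row_size - 1)
    stopf("n_batch_replicates (%d) cannot exceed the %d non-QC slots of the first row",
          cfg$n_batch_replicates, cfg$row_size - 1)
  invisible(cfg)
}

#' Generate a replicate-embedding design sheet
#'
#' Lays out every measurement of the experiment in global run order:
#' conditioning QCs, a pooled QC closing each grid row, one short replicate
#' per row from the second row onward, and a block of batch replicates at the
#' start of every batch after the first. All random selections (which sample
#' is replicated, and at which in-row position) come from the seeded stream
#' in `config`, so the sheet is reproducible.
#'
#' @param config A [design_config()].
#' @return A `design_sheet` data frame with columns `batch`, `run_index`,
#'   `row`, `column`, `sample_id`, `sample_type`, `replicate_group`.
#' @export
generate_design <- function(config) {
  if (!inherits(config, "design_config")) stopf("`config` must be a design_config")
  validate_design_config(config)
  with_seed(config$seed, generate_design_impl(config))
}

generate_design_impl <- function(cfg) {
  R <- cfg$rows_per_batch; C <- cfg$row_size
  K <- if (cfg$n_batches > 1) cfg$n_batch_replicates else 0
  out <- vector("list", cfg$n_batches)
  sample_counter <- 0L
  prev_individuals <- NULL   # data.frame sample_id/row of previous batch
  prev_short_used <- character()
  for (b in seq_len(cfg$n_batches)) {
    n_entries <- cfg$n_conditioning_qc + R * C
    batch <- data.frame(batch = rep(b, n_entries), run_index = NA_integer_,
                        row = NA_integer_, column = NA_integer_,
                        sample_id = NA_character_,
                        sample_type = NA_character_,
                        replicate_group = NA_character_,
                        stringsAsFactors = FALSE)
    i <- 0L
    add <- function(row, col, id, type) {
      i <<- i + 1L
      batch$row[i] <<- as.integer(row); batch$column[i] <<- as.integer(col)
      batch$sample_id[i] <<- id; batch$sample_type[i] <<- type
      batch$replicate_group[i] <<- id
    }
    for (q in seq_len(cfg$n_conditioning_qc))
      add(0L, q, "QC", "conditioningQC")

    # choose the batch replicates from the previous batch
    batch_rep_ids <- character()
    if (b > 1 && K > 0) {
      pool <- prev_individuals[!(prev_individuals$sample_id %in%
                                   prev_short_used), , drop = FALSE]
      if (nrow(pool) < K)
        stopf("batch %d: only %d eligible samples in previous batch for %d batch replicates",
              b, nrow(pool), K)
      if (cfg$stratify_batch_replicates) {
        half <- pool$row <= ceiling(stats::median(prev_individuals$row))
        n1 <- ceiling(K / 2); n2 <- K - n1
        n1 <- min(n1, sum(half)); n2 <- K - n1
        batch_rep_ids <- c(sample(pool$sample_id[half], n1),
                           sample(pool$sample_id[!half], n2))
      } else {
        batch_rep_ids <- sample(pool$sample_id, K)
      }
    }

    # pre-draw short replicate positions and sources row by row
    short_used <- character()
    individuals <- data.frame(sample_id = character(), row = integer(),
                              stringsAsFactors = FALSE)
    short_of_row <- rep(NA_character_, R)
    short_col <- rep(NA_integer_, R)
    for (r in seq_len(R)) {
      # columns 1..C-1 are sample slots, column C is the pooled QC
      slots <- seq_len(C - 1)
      reps_here <- if (r == 1) length(batch_rep_ids) else 0L
      short_here <- r >= 2
      if (short_here) {
        short_col[r] <- sample(slots, 1L)
      }
      for (cc in slots) {
        if (r == 1 && cc <= reps_here) {
          id <- batch_rep_ids[cc]
          add(r, cc, id, "batchReplicate")
        } else if (short_here && cc == short_col[r]) {
          eligible <- if (cfg$short_replicate_source == "previous_row")
            individuals[individuals$row == r - 1, , drop = FALSE]
          else individuals[individuals$row < r, , drop = FALSE]
          eligible <- eligible[!(eligible$sample_id %in% short_used), ,
                               drop = FALSE]
          if (!nrow(eligible))
            stopf("batch %d row %d: no eligible source for a short replicate", b, r)
          src <- eligible$sample_id[sample.int(nrow(eligible), 1L)]
          short_used <- c(short_used, src)
          short_of_row[r] <- src
          add(r, cc, src, "shortReplicate")
        } else {
          sample_counter <- sample_counter + 1L
          id <- sprintf("S%04d", sample_counter)
          individuals <- rbind(individuals,
                               data.frame(sample_id = id, row = r,
                                          stringsAsFactors = FALSE))
          add(r, cc, id, "individual")
        }
      }
      add(r, C, "QC", "pooledQC")
    }
    out[[b]] <- batch
    prev_individuals <- individuals
    prev_short_used <- short_used
  }
  sheet <- do.call(rbind, out)
  sheet$run_index <- seq_len(nrow(sheet))
  class(sheet) <- c("design_sheet", "data.frame")
  attr(sheet, "config") <- cfg
  validate_design_sheet(sheet)
  sheet
}

validate_design_sheet <- function(sheet) {
  if (!all(c("batch", "run_index", "row", "column", "sample_id",
             "sample_type", "replicate_group") %in% names(sheet)))
    stopf("design sheet is missing required columns")
  n <- nrow(sheet)
  if (n == 0) return(invisible(sheet))
  if (anyDuplicated(sheet$run_index)) {
    line <- which(duplicated(sheet$run_index))[1]
    stopf("duplicate run_index %d at sheet line %d", sheet$run_index[line], line)
  }
  if (!identical(as.integer(sheet$run_index), seq_len(n)))
    stopf("run_index must be 1..%d, strictly increasing and gap-free", n)
  bad <- setdiff(unique(sheet$sample_type), SAMPLE_TYPES)
  if (length(bad)) stopf("unknown sample_type(s): %s", paste(bad, collapse = ", "))
  # each short replicate must duplicate an individual from an earlier row of
  # the same batch, and no sample is short-replicated twice in one batch
  for (b in unique(sheet$batch)) {
    sb <- sheet[sheet$batch == b, ]
    sh <- sb[sb$sample_type == "shortReplicate", ]
    if (anyDuplicated(sh$replicate_group))
      stopf("batch %s: a sample is short-replicated more than once", b)
    ind <- sb[sb$sample_type == "individual", ]
    for (j in seq_len(nrow(sh))) {
      src <- ind[ind$replicate_group == sh$replicate_group[j], ]
      if (nrow(src) != 1 || src$row >= sh$row[j])
        stopf("batch %s: short replicate of %s has no individual source in an earlier row",
              b, sh$replicate_group[j])
    }
  }
  invisible(sheet)
}

#' Summarize a design sheet
#'
#' Counts the replicate structure of a design: pooled and conditioning QC
#' measurements, short- and batch-replicate pairs, and the distinct
#' biological samples in each category.
#'
#' @param sheet A `design_sheet` (possibly empty).
#' @return A `design_summary` list with entry counts, pair counts and
#'   distinct-sample counts. `*_measurements` counts both members of each
#'   replicate pair.
#' @export
summarize_design <- function(sheet) {
  type <- sheet$sample_type %||% character()
  shorts <- sheet[type == "shortReplicate", , drop = FALSE]
  breps <- sheet[type == "batchReplicate", , drop = FALSE]
  out <- list(
    n_entries = nrow(sheet) %||% 0L,
    n_batches = length(unique(sheet$batch)),
    pooled_qc = sum(type == "pooledQC"),
    conditioning_qc = sum(type == "conditioningQC"),
    individuals = sum(type == "individual"),
    distinct_individuals = length(unique(sheet$sample_id[type == "individual"])),
    short_replicate_pairs = nrow(shorts),
    short_replicate_measurements = 2L * nrow(shorts),
    distinct_short_replicated = length(unique(shorts$replicate_group)),
    batch_replicate_pairs = nrow(breps),
    batch_replicate_measurements = 2L * nrow(breps),
    distinct_batch_replicated = length(unique(breps$replicate_group)))
  class(out) <- "design_summary"
  out
}

#' @export
print.design_summary <- function(x, ...) {
  cat("Design summary\n")
  cat(sprintf("  batches: %d, total runs: %d\n", x$n_batches, x$n_entries))
  cat(sprintf("  individuals: %d measurements of %d distinct samples\n",
              x$individuals, x$distinct_individuals))
  cat(sprintf("  pooled QC: %d runs (+%d conditioning)\n",
              x$pooled_qc, x$conditioning_qc))
  cat(sprintf("  short replicates: %d pairs (%d measurements)\n",
              x$short_replicate_pairs, x$short_replicate_measurements))
  cat(sprintf("  batch replicates: %d pairs (%d measurements, %d distinct samples)\n",
              x$batch_replicate_pairs, x$batch_replicate_measurements,
              x$distinct_batch_replicated))
  invisible(x)
}

#' Write / read a design sheet as CSV
#'
#' The CSV carries the columns
#' `batch,run_index,row,column,sample_id,sample_type,replicate_group` with a
#' header, so a sheet survives a write/read round trip unchanged.
#'
#' @param sheet A `design_sheet`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a validated `design_sheet`.
#' @export
write_design_csv <- function(sheet, path) {
  cols <- c("batch", "run_index", "row", "column", "sample_id",
            "sample_type", "replicate_group")
  utils::write.csv(as.data.frame(sheet)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("batch", "run_index", "row", "column", "sample_id",
            "sample_type", "replicate_group")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  df <- df[, cols]
  for (cc in c("run_index", "row", "column")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v) && nrow(df))
      stopf("%s: non-integer `%s` at line %d", path, cc, which(is.na(v))[1] + 1L)
    df[[cc]] <- v
  }
  class(df) <- c("design_sheet", "data.frame")
  validate_design_sheet(df)
  df
}

design_annotation <- function(sheet) {
  ann <- as.data.frame(sheet)[, c("batch", "run_index", "row", "column",
                                  "sample_id", "sample_type",
                                  "replicate_group")]
  ann$measurement_id <- measurement_id(ann$run_index)
  ann[ANNOTATION_COLS]
}
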