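# Hierarchical inter-batch integration. Batches (already intra-batch
# normalized) are merged pairwise along a binary tree; at every merge the
# two groups' measurements are concatenated and the replicate-anchored
# adjustment is applied, with the cross-batch replicate pairs linking the
# groups. Two schedules: the balanced tree pairs neighbouring groups layer
# by layer (depth ~ log2 n); the concatenating tree absorbs one batch at a
# time into the growing normalized set (depth n - 1). Both perform exactly
# n - 1 pairwise adjustments.

#' Plan a balanced merge tree
#'
#' Layer 1 pairs neighbouring batches (1,2), (3,4), ...; each subsequent
#' layer pairs neighbouring groups until one group remains. An odd group is
#' carried unmerged to the next layer.
#'
#' @param batch_ids Vector of batch identifiers, in acquisition order.
#' @return A `merge_plan` with `strategy`, `merges` (list of
#'   `left`/`right`/`layer`), `n_merges` and `depth` (number of layers).
#' @export
balanced_plan <- function(batch_ids) {
  if (!length(batch_ids)) stopf("at least one batch id is required")
  if (anyDuplicated(batch_ids)) stopf("duplicated batch ids")
  groups <- lapply(batch_ids, identity)
  merges <- list(); layer <- 0L
  while (length(groups) > 1) {
    layer <- layer + 1L
    nxt <- list()
    i <- 1L
    while (i <= length(groups)) {
      if (i + 1L <= length(groups)) {
        merges[[length(merges) + 1L]] <-
          list(left = unlist(groups[[i]]), right = unlist(groups[[i + 1L]]),
               layer = layer)
        nxt[[length(nxt) + 1L]] <- c(unlist(groups[[i]]),
                                     unlist(groups[[i + 1L]]))
        i <- i + 2L
      } else {  # odd group carried to the next layer
        nxt[[length(nxt) + 1L]] <- unlist(groups[[i]])
        i <- i + 1L
      }
    }
    groups <- nxt
  }
  new_merge_plan("balanced", batch_ids, merges, depth = layer)
}

#' Plan a concatenating merge chain
#'
#' Left-deep chain `((...((1,2),3)...),n)`: batch 2 is merged into batch 1,
#' then each subsequent batch into the growing normalized set. Appending `m`
#' new batches to an executed `n`-batch chain costs exactly `m` further
#' merges.
#'
#' @inheritParams balanced_plan
#' @return A `merge_plan`.
#' @export
concat_plan <- function(batch_ids) {
  if (!length(batch_ids)) stopf("at least one batch id is required")
  if (anyDuplicated(batch_ids)) stopf("duplicated batch ids")
  merges <- list()
  if (length(batch_ids) > 1) {
    for (i in 2:length(batch_ids)) {
      merges[[i - 1L]] <- list(left = batch_ids[seq_len(i - 1L)],
                               right = batch_ids[i], layer = i - 1L)
    }
  }
  new_merge_plan("concatenating", batch_ids, merges,
                 depth = length(merges))
}

new_merge_plan <- function(strategy, batch_ids, merges, depth) {
  structure(list(strategy = strategy, batch_ids = batch_ids,
                 merges = merges, n_merges = length(merges),
                 depth = depth),
            class = "merge_plan")
}

#' @export
print.merge_plan <- function(x, ...) {
  cat(sprintf("merge_plan (%s): %d batches, %d merges, depth %d\n",
              x$strategy, length(x$batch_ids), x$n_merges, x$depth))
  for (m in x$merges)
    cat(sprintf("  layer %d: {%s} + {%s}\n", m$layer,
                paste(m$left, collapse = ","), paste(m$right, collapse = ",")))
  invisible(x)
}

#' Execute a merge plan
#'
#' Runs the hierarchical adjustment: at each merge the two groups'
#' measurements are concatenated, a replicate map is built from the
#' replicate groups with at least two members in the union (by default all
#' such groups — cross-batch links plus any intra-batch pairs — with
#' pooled-QC repeats excluded), and [adjust_group()] is applied. The final
#' assay contains every input measurement exactly once.
#'
#' @param batches Named list of single-batch `hruv_assay` objects (log2
#'   scale, intra-batch normalized), names matching the plan's batch ids.
#' @param plan A [balanced_plan()] or [concat_plan()].
#' @param k Unwanted factors per merge (default 5).
#' @param controls Negative-control metabolites (default all).
#' @param replicate_policy `"all"` (default) uses every multi-member
#'   replicate group in the union; `"cross_only"` restricts to groups
#'   spanning both sides of the merge.
#' @param include_qc Treat pooled-QC repeats as a replicate group
#'   (default `FALSE`).
#' @param k_policy Passed to [ruv3_adjust()].
#' @return List with `assay` (the merged `hruv_assay`) and `log` (one row
#'   per merge: layer, sides, group counts, k requested and used).
#' @export
execute_plan <- function(batches, plan, k = 5, controls = NULL,
                         replicate_policy = c("all", "cross_only"),
                         include_qc = FALSE,
                         k_policy = c("cap", "error")) {
  replicate_policy <- match.arg(replicate_policy)
  k_policy <- match.arg(k_policy)
  if (!inherits(plan, "merge_plan")) stopf("`plan` must be a merge_plan")
  if (is_assay(batches)) batches <- split_batches(batches)
  if (is.null(names(batches)) && length(batches) == length(plan$batch_ids))
    names(batches) <- as.character(plan$batch_ids)
  miss <- setdiff(as.character(plan$batch_ids), names(batches))
  if (length(miss))
    stopf("plan refers to batch(es) not supplied: %s", paste(miss, collapse = ", "))
  pool <- batches  # current groups, keyed by their batch-id signature
  key <- function(ids) paste(ids, collapse = "|")
  pool <- stats::setNames(pool, vapply(names(batches), key, ""))
  log <- NULL
  for (m in plan$merges) {
    lk <- key(m$left); rk <- key(m$right)
    if (!lk %in% names(pool) || !rk %in% names(pool))
      stopf("merge layer %d: group not available (internal plan error)", m$layer)
    merged <- bind_assays(pool[[lk]], pool[[rk]])
    labels <- replicate_labels(
      merged$annotation,
      scope = if (replicate_policy == "cross_only") "cross" else "all",
      include_qc = include_qc)
    if (attr(labels, "n_replicated") == 0)
      stopf("merge {%s} + {%s}: no replicate group links or spans the union",
            paste(m$left, collapse = ","), paste(m$right, collapse = ","))
    map <- build_replicate_matrix(labels)
    k_used <- min(k, replicate_residual_rank(map))
    merged$values <- t(adjust_group(t(merged$values), map,
                                    controls = controls, k = k,
                                    k_policy = k_policy))
    pool[[lk]] <- NULL; pool[[rk]] <- NULL
    pool[[key(c(m$left, m$right))]] <- merged
    log <- rbind(log, data.frame(
      layer = m$layer,
      left = paste(m$left, collapse = ","),
      right = paste(m$right, collapse = ","),
      n_measurements = ncol(merged$values),
      n_replicate_groups = attr(labels, "n_replicated"),
      k_requested = k, k_used = k_used,
      stringsAsFactors = FALSE))
  }
  if (length(pool) != 1)
    stopf("plan did not reduce to a single group (internal plan error)")
  list(assay = pool[[1]], log = log %||% data.frame())
}

#' Parse a full method tag
#'
#' Decomposes a two-level method tag of the form
#' `<intrabatch>[Short]_batch_<H|Hc>` (or a single-level intra-batch tag)
#' into the intra-batch specification and the merge-tree strategy. `_H`
#' denotes the balanced tree, `_Hc` the concatenating tree.
#'
#' @param tag Method tag, e.g. `"loessAllShort_batch_Hc"`.
#' @return List with `intrabatch` (tag string), `smoother`, `short`
#'   (logical), and `strategy` (`"balanced"`, `"concatenating"` or `NULL`
#'   for intra-batch-only methods).
#' @export
parse_method_tag <- function(tag) {
  if (!is.character(tag) || length(tag) != 1 || !nzchar(tag))
    stopf("method tag must be a single non-empty string")
  parts <- strsplit(tag, "_", fixed = TRUE)[[1]]
  grammar <- paste0(
    "expected '<intra>[Short]' or '<intra>[Short]_batch_<H|Hc>' with <intra> in {",
    paste(INTRABATCH_TAGS, collapse = ", "), "}")
  if (length(parts) == 1) {
    spec <- parse_intrabatch_tag(parts[1])
    strategy <- NULL
  } else if (length(parts) == 3 && parts[2] == "batch" &&
             parts[3] %in% c("H", "Hc")) {
    spec <- parse_intrabatch_tag(parts[1])
    strategy <- if (parts[3] == "H") "balanced" else "concatenating"
  } else {
    stopf("malformed method tag '%s'; %s", tag, grammar)
  }
  list(intrabatch = parts[1], smoother = spec$smoother,
       kind = spec$kind, short = spec$short, strategy = strategy)
}
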