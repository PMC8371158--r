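# Replicate-anchored removal of unwanted variation (RUV-III style).
#
# Model, on the mean-centred measurements-by-metabolites matrix Z (S x M):
#
#   Z = X beta + W alpha + eps
#
# where X (S x p) holds the unobserved factors of interest, W (S x k) the
# unwanted-factor scores and alpha (k x M) their loadings. Technical
# replicates of one biological sample share a row of X, so the component of
# Z that varies *within* replicate groups is free of biology: loadings are
# estimated from the top-k right singular directions of the
# replicate-residualized matrix R_M Z (R_M projects out replicate-group
# means), scores by regressing the negative-control columns of Z on the
# control columns of alpha-hat, and W-hat alpha-hat is subtracted.
# Per-metabolite means are removed before and restored after the fit.
#
# Orientation: these functions take measurements in ROWS and metabolites in
# COLUMNS (Z is S x M); the assay container stores the transpose.

#' Build the replicate indicator matrix
#'
#' One row per measurement, one column per distinct biological sample; each
#' row has exactly one 1. Columns with sum >= 2 are replicate groups; the
#' replicate residual space has rank S minus the number of columns.
#'
#' @param x A character vector of replicate-group labels, or an annotation
#'   data frame (or `hruv_assay`) with a `replicate_group` column.
#' @return A `replicate_map` with elements `indicator` (S x G binary
#'   matrix) and `group_ids`.
#' @export
build_replicate_matrix <- function(x) {
  labels <- if (is_assay(x)) x$annotation$replicate_group
  else if (is.data.frame(x)) x$replicate_group
  else x
  if (is.null(labels) || !length(labels))
    stopf("no replicate-group labels supplied")
  if (anyNA(labels) || any(!nzchar(labels)))
    stopf("missing replicate-group label at position %d",
          which(is.na(labels) | !nzchar(labels))[1])
  groups <- unique(labels)
  ind <- matrix(0, nrow = length(labels), ncol = length(groups),
                dimnames = list(NULL, groups))
  ind[cbind(seq_along(labels), match(labels, groups))] <- 1
  structure(list(indicator = ind, group_ids = groups),
            class = "replicate_map")
}

#' @export
print.replicate_map <- function(x, ...) {
  sizes <- colSums(x$indicator)
  cat(sprintf("replicate_map: %d measurements, %d groups (%d with replicates), residual rank %d\n",
              nrow(x$indicator), ncol(x$indicator), sum(sizes >= 2),
              nrow(x$indicator) - ncol(x$indicator)))
  invisible(x)
}

#' Rank of the replicate residual space
#'
#' The number of independent within-replicate-group contrasts a map
#' provides: measurements minus distinct samples. This bounds the number of
#' unwanted factors estimable from the replicates.
#'
#' @param map A [build_replicate_matrix()] result.
#' @return Integer rank.
#' @export
replicate_residual_rank <- function(map) {
  nrow(map$indicator) - ncol(map$indicator)
}

#' Remove and restore per-metabolite means
#'
#' `mean_center` subtracts each metabolite's mean over all S measurements;
#' `restore_mean` adds it back, so the round trip is exact.
#'
#' @param Y Numeric matrix, measurements x metabolites.
#' @param Z Centred matrix as returned by `mean_center`.
#' @param means Per-metabolite mean vector.
#' @return `mean_center`: list with `Z` and `means`; `restore_mean`: the
#'   original-scale matrix.
#' @export
mean_center <- function(Y) {
  means <- colMeans(Y, na.rm = TRUE)
  list(Z = sweep(Y, 2L, means, `-`), means = means)
}

#' @rdname mean_center
#' @export
restore_mean <- function(Z, means) {
  sweep(Z, 2L, means, `+`)
}

#' RUV adjustment of a mean-centred matrix
#'
#' Estimates the unwanted component `W alpha` from the replicate structure
#' and negative controls and returns `Z - W-hat alpha-hat`. With `k = 0` the
#' input is returned unchanged.
#'
#' @param Z Mean-centred matrix, measurements x metabolites.
#' @param map A [build_replicate_matrix()] result aligned to the rows of `Z`.
#' @param controls Negative-control metabolites: column indices, logical
#'   mask or names; default all metabolites.
#' @param k Number of unwanted factors to remove (default 5).
#' @param k_policy What to do when `k` exceeds the replicate residual rank:
#'   `"cap"` (default; reduce with a warning) or `"error"`.
#' @return The adjusted matrix, same dimensions as `Z`.
#' @export
ruv3_adjust <- function(Z, map, controls = NULL, k = 5,
                        k_policy = c("cap", "error")) {
  k_policy <- match.arg(k_policy)
  if (!is.matrix(Z)) stopf("`Z` must be a matrix")
  if (!inherits(map, "replicate_map")) stopf("`map` must be a replicate_map")
  if (nrow(map$indicator) != nrow(Z))
    stopf("replicate map has %d rows but Z has %d", nrow(map$indicator), nrow(Z))
  if (!is_count(k)) stopf("k must be a non-negative count")
  if (k == 0) return(Z)
  ctl <- resolve_controls(controls, Z)
  rank <- replicate_residual_rank(map)
  if (rank == 0)
    stopf("no replicate information: every replicate group has a single member")
  if (k > rank) {
    if (k_policy == "error")
      stopf("k = %d exceeds the replicate residual rank %d", k, rank)
    warnf("k capped from %d to the replicate residual rank %d", k, rank)
    k <- rank
  }
  M <- map$indicator
  # R_M Z: residual after projecting rows onto the replicate-group means
  gmean <- M %*% (crossprod(M, Z) / colSums(M))
  R <- Z - gmean
  sv <- svd(R, nu = 0, nv = k)
  # guard against removing directions that are numerically zero
  tol <- max(dim(R)) * .Machine$double.eps * sv$d[1]
  k_eff <- min(k, sum(sv$d > max(tol, 0)))
  if (k_eff < k) {
    warnf("k capped from %d to the numerical rank %d of the replicate residual",
          k, k_eff)
    k <- k_eff
    if (k == 0) return(Z)
  }
  alpha <- t(sv$v[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)],
                                                    each = ncol(Z)))
  ac <- alpha[, ctl, drop = FALSE]
  gram <- tcrossprod(ac)
  W <- tryCatch(Z[, ctl, drop = FALSE] %*% t(ac) %*% solve(gram),
                error = function(e)
                  stopf("singular control regression (k = %d, %d controls): %s",
                        k, length(ctl), conditionMessage(e)))
  Z - W %*% alpha
}

resolve_controls <- function(controls, Z) {
  M <- ncol(Z)
  if (is.null(controls)) return(seq_len(M))
  if (is.logical(controls)) {
    if (length(controls) != M) stopf("logical `controls` must have length %d", M)
    controls <- which(controls)
  } else if (is.character(controls)) {
    idx <- match(controls, colnames(Z))
    if (anyNA(idx)) stopf("unknown control metabolite '%s'",
                          controls[which(is.na(idx))[1]])
    controls <- idx
  }
  if (!length(controls)) stopf("`controls` must name at least one metabolite")
  if (any(controls < 1 | controls > M)) stopf("control index out of range")
  as.integer(controls)
}

#' Replicate-anchored adjustment of a measurement group
#'
#' The full per-merge adjustment: per-metabolite means are removed, the
#' centred matrix is RUV-adjusted using the replicate structure, and the
#' means are restored.
#'
#' @inheritParams ruv3_adjust
#' @param Y Matrix, measurements x metabolites (not centred).
#' @return The adjusted matrix, same dimensions and row/column order as `Y`.
#' @export
adjust_group <- function(Y, map, controls = NULL, k = 5,
                         k_policy = c("cap", "error")) {
  mc <- mean_center(Y)
  Zhat <- ruv3_adjust(mc$Z, map, controls = controls, k = k,
                      k_policy = k_policy)
  restore_mean(Zhat, mc$means)
}

#' Data-driven selection of negative-control metabolites
#'
#' Ranks metabolites by the strength of their association with a binary
#' phenotype, per batch, and returns the `n_controls` least-associated ones.
#' The association score is an ordinary two-sample t statistic on the
#' individual samples of each batch; per-batch ranks of |t| are averaged
#' across batches. Batches where one phenotype class is absent are skipped
#' with a warning.
#'
#' @param batches A list of `hruv_assay` objects (log2 scale) or one merged
#'   assay.
#' @param phenotype Named binary vector (0/1 or logical), names = sample ids
#'   of the individual samples.
#' @param n_controls Number of control metabolites to return.
#' @return Character vector of metabolite ids, least phenotype-associated.
#' @export
select_negative_controls <- function(batches, phenotype, n_controls) {
  if (is_assay(batches)) batches <- split_batches(batches)
  lapply(batches, assert_assay)
  mets <- rownames(batches[[1]]$values)
  if (!is_count(n_controls, min = 1)) stopf("n_controls must be a count >= 1")
  if (n_controls > length(mets))
    stopf("n_controls (%d) exceeds the %d available metabolites",
          n_controls, length(mets))
  if (n_controls == length(mets)) return(mets)
  rank_sum <- numeric(length(mets)); n_used <- 0L
  for (b in seq_along(batches)) {
    a <- batches[[b]]
    idx <- which(a$annotation$sample_type == "individual")
    ph <- phenotype[a$annotation$sample_id[idx]]
    if (length(unique(ph[!is.na(ph)])) < 2) {
      warnf("batch %s skipped: only one phenotype class present",
            unique(a$annotation$batch))
      next
    }
    g1 <- idx[which(ph == 1)]; g0 <- idx[which(ph == 0)]
    tstat <- vapply(seq_along(mets), function(i) {
      x1 <- a$values[i, g1]; x0 <- a$values[i, g0]
      x1 <- x1[!is.na(x1)]; x0 <- x0[!is.na(x0)]
      if (length(x1) < 2 || length(x0) < 2) return(0)
      se <- sqrt(stats::var(x1) / length(x1) + stats::var(x0) / length(x0))
      if (se == 0) return(0)
      (mean(x1) - mean(x0)) / se
    }, numeric(1))
    rank_sum <- rank_sum + rank(abs(tstat))
    n_used <- n_used + 1L
  }
  if (n_used == 0) stopf("no batch had both phenotype classes")
  mets[order(rank_sum)][seq_len(n_controls)]
}
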