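# Shared fixtures and independent oracle implementations used across the
# suite. The oracles are deliberately written from the defining formulas
# (explicit projectors, eigendecompositions, pair enumeration), not by
# calling the package's own code paths.

# Build a small assay from a metabolite x measurement matrix.
make_assay <- function(values, batch = 1L, sample_type = NULL,
                       replicate_group = NULL, sample_id = NULL,
                       run_index = NULL, scale = "log2") {
  n <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("m%02d", seq_len(nrow(values)))
  run_index <- run_index %||% seq_len(n)
  sample_type <- sample_type %||% rep("individual", n)
  sample_id <- sample_id %||% sprintf("S%03d", seq_len(n))
  replicate_group <- replicate_group %||% sample_id
  ann <- data.frame(batch = rep_len(batch, n), run_index = run_index,
                    row = rep(1L, n), column = seq_len(n),
                    sample_id = sample_id, sample_type = sample_type,
                    replicate_group = replicate_group,
                    stringsAsFactors = FALSE)
  ann$measurement_id <- sprintf("b%s_r%04d", ann$batch, ann$run_index)
  hruv_assay(values, ann, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force RUV adjustment from explicit projector / least-squares
# algebra: replicate projector via solve(), loadings via the eigenvectors
# of the residual Gram matrix, scores via an explicit normal-equation
# solve. Any basis of the same loading row space yields the same
# adjustment, so this is comparable to the package output to numerical
# precision.
oracle_ruv3 <- function(Z, groups, ctl = seq_len(ncol(Z)), k) {
  if (k == 0) return(Z)
  G <- unique(groups)
  M <- outer(groups, G, `==`) * 1
  PM <- M %*% solve(t(M) %*% M) %*% t(M)
  R <- (diag(nrow(Z)) - PM) %*% Z
  ee <- eigen(t(R) %*% R, symmetric = TRUE)
  V <- ee$vectors[, seq_len(k), drop = FALSE]
  d <- sqrt(pmax(ee$values[seq_len(k)], 0))
  alpha <- diag(d, nrow = k) %*% t(V)
  ac <- alpha[, ctl, drop = FALSE]
  W <- Z[, ctl, drop = FALSE] %*% t(ac) %*% solve(ac %*% t(ac))
  Z - W %*% alpha
}

# Brute-force adjusted Rand index: enumerate every pair of elements into
# the four agreement classes, then apply the chance-corrected index in its
# expectation form.
oracle_ari <- function(a, b) {
  n <- length(a)
  A <- B <- C <- D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) A <- A + 1
    else if (sa && !sb) B <- B + 1
    else if (!sa && sb) C <- C + 1
    else D <- D + 1
  }
  total <- A + B + C + D
  expected <- (A + B) * (A + C) / total
  maximum <- (2 * A + B + C) / 2
  if (maximum == expected) return(1)
  (A - expected) / (maximum - expected)
}

# A small two-batch scenario with explicit replicate links, used by the
# RUV and hierarchy tests. Batch 2 equals batch 1's biology plus a
# constant per-metabolite offset; `n_links` samples are measured in both.
make_offset_batches <- function(n_met = 8, n_per_batch = 12, n_links = 5,
                                offset = NULL, seed = 42) {
  set.seed(seed)
  offset <- offset %||% rnorm(n_met, 0, 2)
  bio <- matrix(rnorm(n_met * n_per_batch, 10, 1), nrow = n_met)
  ids <- sprintf("S%03d", seq_len(2 * n_per_batch - n_links))
  ids1 <- ids[seq_len(n_per_batch)]
  # the first n_links samples of batch 1 are re-measured in batch 2
  ids2 <- c(ids1[seq_len(n_links)], ids[(n_per_batch + 1):(2 * n_per_batch - n_links)])
  bio2 <- cbind(bio[, seq_len(n_links), drop = FALSE],
                matrix(rnorm(n_met * (n_per_batch - n_links), 10, 1), nrow = n_met))
  v1 <- bio
  v2 <- bio2 + offset
  rownames(v1) <- rownames(v2) <- sprintf("m%02d", seq_len(n_met))
  types2 <- c(rep("batchReplicate", n_links),
              rep("individual", n_per_batch - n_links))
  a1 <- make_assay(v1, batch = 1L, sample_id = ids1, run_index = seq_len(n_per_batch))
  a2 <- make_assay(v2, batch = 2L, sample_id = ids2, sample_type = types2,
                   run_index = n_per_batch + seq_len(n_per_batch))
  list(batches = list(`1` = a1, `2` = a2), offset = offset,
       linked = ids1[seq_len(n_links)])
}
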