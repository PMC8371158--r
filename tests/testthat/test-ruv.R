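test_that("replicate indicator has one 1 per row and the right group sizes", {
  map <- build_replicate_matrix(c("A", "A", "B"))
  expect_identical(dim(map$indicator), c(3L, 2L))
  expect_true(all(rowSums(map$indicator) == 1))
  expect_identical(unname(colSums(map$indicator)), c(2, 1))
  expect_identical(replicate_residual_rank(map), 1L)

  # all distinct: identity-like, residual rank zero
  m2 <- build_replicate_matrix(letters[1:4])
  expect_identical(replicate_residual_rank(m2), 0L)
  expect_identical(unname(m2$indicator), diag(4))

  expect_error(build_replicate_matrix(character()), "labels")
  expect_error(build_replicate_matrix(c("A", NA)), "missing")
})

test_that("mean centring and restoration round-trip exactly", {
  set.seed(8)
  Y <- matrix(rnorm(60, 50, 4), nrow = 10)
  mc <- mean_center(Y)
  expect_equal(max(abs(colMeans(mc$Z))), 0, tolerance = 1e-12)
  expect_identical(restore_mean(mc$Z, mc$means), Y)
  # a constant metabolite centres to zero with its mean recorded
  Yc <- cbind(rep(3, 5), rnorm(5))
  mcc <- mean_center(Yc)
  expect_equal(mcc$Z[, 1], rep(0, 5))
  expect_equal(mcc$means[1], 3)
})

test_that("ruv3_adjust matches the brute-force projector oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    groups <- c("a", "a", "b", "b", "c", "c", "d", "e", "f", "g")
    Z <- scale(matrix(rnorm(10 * 8), nrow = 10), scale = FALSE)
    map <- build_replicate_matrix(groups)
    for (k in c(1, 2, 3)) {
      ours <- ruv3_adjust(Z, map, k = k)
      theirs <- oracle_ruv3(Z, groups, k = k)
      expect_equal(ours, theirs, tolerance = 1e-10)
    }
    ctl <- c(1, 3, 5, 7)
    expect_equal(ruv3_adjust(Z, map, controls = ctl, k = 2),
                 oracle_ruv3(Z, groups, ctl = ctl, k = 2),
                 tolerance = 1e-10)
  }
})

test_that("k = 0 is the exact identity and rank-0 maps are rejected", {
  set.seed(9)
  Z <- matrix(rnorm(40), nrow = 8)
  map <- build_replicate_matrix(c("a", "a", "b", "b", "c", "d", "e", "f"))
  expect_identical(ruv3_adjust(Z, map, k = 0), Z)
  singletons <- build_replicate_matrix(letters[1:8])
  expect_error(ruv3_adjust(Z, singletons, k = 1), "replicate")
  expect_error(ruv3_adjust(Z, map, k = 5, k_policy = "error"), "residual rank")
  expect_warning(capped <- ruv3_adjust(Z, map, k = 5, k_policy = "cap"), "capped")
  expect_identical(dim(capped), dim(Z))
})

test_that("a planted unwanted factor is removed exactly in the noiseless case", {
  set.seed(10)
  n_met <- 8; n_rep <- 4; n_single <- 6
  S <- 2 * n_rep + n_single
  # replicate pairs share the biology row; controls carry no biology
  bio <- matrix(0, nrow = S, ncol = n_met)
  bio_rows <- matrix(rnorm(n_rep * 3), nrow = n_rep)
  bio[seq_len(n_rep), 1:3] <- bio_rows
  bio[n_rep + seq_len(n_rep), 1:3] <- bio_rows
  bio[2 * n_rep + seq_len(n_single), 1:3] <- matrix(rnorm(n_single * 3), nrow = n_single)
  alpha <- matrix(rnorm(n_met), nrow = 1)
  w <- matrix(rnorm(S), ncol = 1)
  Z <- scale(bio + w %*% alpha, scale = FALSE)
  groups <- c(sprintf("r%d", seq_len(n_rep)), sprintf("r%d", seq_len(n_rep)),
              sprintf("s%d", seq_len(n_single)))
  map <- build_replicate_matrix(groups)
  out <- ruv3_adjust(Z, map, controls = 4:8, k = 1)
  # replicate pairs agree after adjustment, and control columns are biology-free
  for (r in seq_len(n_rep))
    expect_equal(out[r, ], out[n_rep + r, ], tolerance = 1e-6)
  ctr <- scale(out[, 4:8], scale = FALSE)
  expect_lt(max(abs(ctr)), 1e-6)
})

test_that("adjust_group removes a constant between-batch offset through replicate links", {
  sc <- make_offset_batches(seed = 42)
  merged <- bind_assays(sc$batches)
  Y <- t(merged$values)
  labels <- merged$annotation$replicate_group
  map <- build_replicate_matrix(labels)
  pre_gap <- colMeans(Y[merged$annotation$batch == 2, ]) -
    colMeans(Y[merged$annotation$batch == 1, ])
  out <- adjust_group(Y, map, k = 1)
  post_gap <- colMeans(out[merged$annotation$batch == 2, ]) -
    colMeans(out[merged$annotation$batch == 1, ])
  # the offset component of the gap is annihilated; compare against the
  # explicit rank-one removal oracle
  oracle <- restore_mean(oracle_ruv3(mean_center(Y)$Z, labels, k = 1),
                         mean_center(Y)$means)
  expect_equal(out, oracle, tolerance = 1e-10)
  proj <- function(g) sum(g * sc$offset) / sqrt(sum(sc$offset^2))
  expect_lt(abs(proj(post_gap)), 1e-6 * abs(proj(pre_gap)))
  expect_identical(dim(out), dim(Y))
})

test_that("two identical concatenated batches pass through almost unchanged", {
  set.seed(12)
  v <- matrix(rnorm(8 * 6, 10), nrow = 8,
              dimnames = list(sprintf("m%d", 1:8), NULL))
  a1 <- make_assay(v, batch = 1L, sample_id = sprintf("S%d", 1:6))
  a2 <- make_assay(v, batch = 2L, sample_id = sprintf("S%d", 1:6),
                   sample_type = rep("batchReplicate", 6), run_index = 7:12)
  merged <- bind_assays(a1, a2)
  Y <- t(merged$values)
  map <- build_replicate_matrix(merged$annotation$replicate_group)
  # replicate pairs are exactly identical, so the replicate residual is
  # numerically zero and there is no unwanted variation to estimate
  out <- suppressWarnings(adjust_group(Y, map, k = 2))
  expect_equal(out, Y, tolerance = 1e-6)
})

test_that("adjust_group commutes with measurement reordering", {
  sc <- make_offset_batches(seed = 24)
  merged <- bind_assays(sc$batches)
  Y <- t(merged$values)
  labels <- merged$annotation$replicate_group
  out <- adjust_group(Y, build_replicate_matrix(labels), k = 1)
  perm <- sample(nrow(Y))
  out_perm <- adjust_group(Y[perm, ], build_replicate_matrix(labels[perm]), k = 1)
  expect_equal(out_perm, out[perm, ], tolerance = 1e-9)
})

test_that("with full controls and maximal k, replicate groups collapse to their means", {
  set.seed(13)
  groups <- c("a", "a", "b", "b", "c", "c", "d", "d")
  Z <- scale(matrix(rnorm(8 * 6), nrow = 8), scale = FALSE)
  map <- build_replicate_matrix(groups)
  out <- ruv3_adjust(Z, map, k = replicate_residual_rank(map))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    expect_equal(out[idx[1], ], out[idx[2], ], tolerance = 1e-8)
  }
})

test_that("negative-control selection excludes truly associated metabolites", {
  n_met <- 50; n_per <- 30
  for (seed in 1:5) {
    set.seed(seed * 100)
    mets <- sprintf("m%02d", seq_len(n_met))
    assoc <- mets[1:5]
    make_batch <- function(b) {
      ph <- rep(c(0, 1), each = n_per)
      v <- matrix(rnorm(n_met * 2 * n_per, 10, 0.3), nrow = n_met,
                  dimnames = list(mets, NULL))
      v[1:5, ph == 1] <- v[1:5, ph == 1] + 2
      ids <- sprintf("S%d_%d", b, seq_len(2 * n_per))
      a <- make_assay(v, batch = b, sample_id = ids,
                      run_index = (b - 1) * 2 * n_per + seq_len(2 * n_per))
      list(assay = a, ph = stats::setNames(ph, ids))
    }
    b1 <- make_batch(1); b2 <- make_batch(2)
    ph <- c(b1$ph, b2$ph)
    ctl <- select_negative_controls(list(b1$assay, b2$assay), ph, 40)
    expect_length(ctl, 40)
    expect_length(intersect(ctl, assoc), 0)
  }
  # trivial and error cases
  b <- make_assay(matrix(rnorm(50 * 10, 10), nrow = 50,
                         dimnames = list(sprintf("m%02d", 1:50), NULL)))
  ph_all <- stats::setNames(rep(c(0, 1), 5), b$annotation$sample_id)
  expect_identical(select_negative_controls(list(b), ph_all, 50),
                   rownames(b$values))
  expect_error(select_negative_controls(list(b), ph_all, 51), "exceeds")
})
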