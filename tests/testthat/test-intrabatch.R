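qc_every_11 <- function(n) ifelse(seq_len(n) %% 11 == 0, "pooledQC", "individual")

test_that("ratio adjustment divides by the bracketing pooled QC", {
  # QCs at runs 11 and 22 (M = 11): runs up to the midpoint use the earlier
  # QC, later runs the next one; the QC run itself maps to 1
  n <- 22
  v <- matrix(100, nrow = 1, ncol = n, dimnames = list("m1", NULL))
  v[1, 11] <- 100; v[1, 22] <- 200
  v[1, 12] <- 200   # l = L + 1 with P_L = 100 -> 2.0
  v[1, 16] <- 300   # l = L + 5 <= L + M/2 -> uses P_L = 100 -> 3.0
  v[1, 17] <- 300   # l = L + 6 >  L + M/2 -> uses P_{L+M} = 200 -> 1.5
  a <- make_assay(v, sample_type = qc_every_11(n),
                  sample_id = ifelse(seq_len(n) %% 11 == 0, "QC", sprintf("S%02d", seq_len(n))),
                  replicate_group = ifelse(seq_len(n) %% 11 == 0, "QC", sprintf("S%02d", seq_len(n))),
                  scale = "raw")
  out <- ratio_adjust(a)
  expect_equal(out$values[1, 12], 2.0)
  expect_equal(out$values[1, 16], 3.0)
  expect_equal(out$values[1, 17], 1.5)
  expect_equal(out$values[1, 11], 1.0)
  expect_equal(out$values[1, 22], 1.0)
  # zero QC signal is an error, as is log-scale input
  v0 <- v; v0[1, 11] <- 0
  a0 <- make_assay(v0, sample_type = qc_every_11(n), scale = "raw")
  expect_error(ratio_adjust(a0), "non-positive")
  expect_error(ratio_adjust(make_assay(v, sample_type = qc_every_11(n))), "raw")
})

test_that("smoothers leave constant signals untouched and flatten exact linear drift", {
  n <- 30
  run <- seq_len(n)
  const <- matrix(5, nrow = 1, ncol = n, dimnames = list("m1", NULL))
  a_const <- make_assay(const)
  for (kind in c("loess", "rlm")) {
    out <- smooth_adjust(a_const, smoother_spec(kind, "all_samples"))
    expect_equal(out$values, const, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # exact line y = 2 + 0.1 run: the robust fit recovers the line, the
  # adjusted series is the batch median with zero residual slope
  lin <- matrix(2 + 0.1 * run, nrow = 1, dimnames = list("m1", NULL))
  a_lin <- make_assay(lin)
  out <- smooth_adjust(a_lin, smoother_spec("rlm", "all_samples"))
  expect_equal(unname(out$values[1, ]), rep(median(lin), n), tolerance = 1e-8)
  expect_lt(abs(coef(lm(out$values[1, ] ~ run))[2]), 1e-8)
})

test_that("the loess adjustment equals an independent recomputation of the correction rule", {
  set.seed(14)
  n <- 20
  v <- matrix(rnorm(2 * n, 10), nrow = 2, dimnames = list(c("m1", "m2"), NULL))
  a <- make_assay(v)
  out <- smooth_adjust(a, smoother_spec("loess", "all_samples"))
  run <- seq_len(n)
  for (i in 1:2) {
    fit <- stats::loess(v[i, ] ~ run, span = 0.75, degree = 2,
                        control = stats::loess.control(surface = "direct"))
    expected <- v[i, ] + (median(v[i, ]) - predict(fit, data.frame(run = run)))
    expect_equal(unname(out$values[i, ]), unname(expected), tolerance = 1e-8)
  }
})

test_that("pooled-QC-scope fits evaluate at sample positions and clamp at the edges", {
  set.seed(15)
  n <- 66
  type <- qc_every_11(n)
  drift <- 0.2 * seq_len(n)
  v <- matrix(10 + drift, nrow = 1, dimnames = list("m1", NULL))
  a <- make_assay(v, sample_type = type)
  out <- smooth_adjust(a, smoother_spec("rlm", "pooled_qc"))
  # the QC-only linear fit recovers the common drift, so all samples land
  # on the batch median
  expect_equal(unname(out$values[1, ]), rep(median(v), n), tolerance = 1e-6)
  # loess with QC scope must clamp predictions outside the QC run span
  out2 <- smooth_adjust(a, smoother_spec("loess", "pooled_qc"))
  expect_false(anyNA(out2$values))
})

test_that("insufficient fitting points and unknown tags raise errors", {
  a <- make_assay(matrix(1:3, nrow = 1, dimnames = list("m1", NULL)))
  expect_error(smooth_adjust(a, smoother_spec("loess", "all_samples")), ">= 4")
  b <- make_assay(matrix(rnorm(10, 5), nrow = 1, dimnames = list("m1", NULL)))
  expect_error(smooth_adjust(b, smoother_spec("loess", "pooled_qc")), "pooled QC")
  expect_error(run_intrabatch(b, "foo"), "valid tags")
})

test_that("drift correction with all-sample scope decouples signal from run order", {
  set.seed(16)
  n <- 60; n_met <- 20
  run <- seq_len(n)
  slopes <- rnorm(n_met, 0, 0.1)
  v <- 10 + outer(slopes, run) + matrix(rnorm(n_met * n, 0, 0.3), nrow = n_met)
  rownames(v) <- sprintf("m%02d", seq_len(n_met))
  a <- make_assay(v)
  out <- smooth_adjust(a, smoother_spec("loess", "all_samples"))
  rho <- apply(out$values, 1, function(y) cor(y, run, method = "spearman"))
  expect_lt(median(abs(rho)), 0.1)
  raw_rho <- apply(v, 1, function(y) cor(y, run, method = "spearman"))
  expect_gt(median(abs(raw_rho)), 0.5)
})

test_that("short-replicate RUV needs pairs, respects k = 0, and preserves shape", {
  set.seed(17)
  n <- 22; n_met <- 6
  type <- qc_every_11(n)
  ids <- sprintf("S%02d", seq_len(n))
  ids[15] <- ids[3]   # one short replicate of sample 3
  type[15] <- "shortReplicate"
  ids[type == "pooledQC"] <- "QC"
  v <- matrix(rnorm(n_met * n, 10), nrow = n_met,
              dimnames = list(sprintf("m%d", seq_len(n_met)), NULL))
  v[, 15] <- v[, 3] + rnorm(n_met, 0, 0.01)
  a <- make_assay(v, sample_type = type, sample_id = ids, replicate_group = ids)
  expect_equal(ruv_short(a, k = 0)$values, v, ignore_attr = TRUE)
  out <- suppressWarnings(ruv_short(a, k = 1))
  expect_identical(dim(out$values), dim(v))
  # no replicate pairs at all: explicit error telling the user to skip
  b <- make_assay(v, sample_type = qc_every_11(n))
  expect_error(ruv_short(b, k = 1), "skip")
})

test_that("short-replicate RUV removes a planted rank-one disturbance from a batch", {
  set.seed(18)
  n_met <- 10; n <- 24
  type <- rep("individual", n)
  ids <- sprintf("S%02d", seq_len(n))
  # three short-replicate pairs
  for (p in 1:3) { ids[20 + p] <- ids[p]; type[20 + p] <- "shortReplicate" }
  bio <- matrix(rnorm(n_met * n, 10), nrow = n_met)
  bio[, 21:23] <- bio[, 1:3]
  alpha <- rnorm(n_met)
  w <- rnorm(n)
  v <- bio + outer(alpha, w)
  rownames(v) <- sprintf("m%02d", seq_len(n_met))
  a <- make_assay(v, sample_type = type, sample_id = ids, replicate_group = ids)
  out <- ruv_short(a, k = 1)
  for (p in 1:3)
    expect_equal(out$values[, 20 + p], out$values[, p], tolerance = 1e-6)
})

test_that("method tags compose the documented smoother scope and RUV step", {
  p <- parse_method_tag("loessAllShort_batch_Hc")
  expect_identical(p$kind, "loess")
  expect_identical(p$smoother$scope, "all_samples")
  expect_true(p$short)
  expect_identical(p$strategy, "concatenating")

  p2 <- parse_method_tag("rlm_batch_H")
  expect_identical(p2$kind, "rlm")
  expect_identical(p2$smoother$scope, "pooled_qc")
  expect_false(p2$short)
  expect_identical(p2$strategy, "balanced")

  p3 <- parse_method_tag("loessSampleShort")
  expect_identical(p3$smoother$scope, "all_samples")
  expect_true(p3$short)
  expect_null(p3$strategy)

  expect_identical(parse_method_tag("ratio")$kind, "ratio")
  expect_error(parse_method_tag("foo_bar"), "malformed|expected")
  expect_error(parse_method_tag("loess_batch_X"), "malformed")
})
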