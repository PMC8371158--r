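test_that("the reference 15-batch geometry yields the expected replicate counts", {
  cfg <- design_config(n_batches = 15, rows_per_batch = 8, row_size = 11,
                       n_batch_replicates = 5, seed = 7)
  sheet <- generate_design(cfg)
  s <- summarize_design(sheet)
  # 5 batch replicates at each of the 14 transitions, every one a distinct
  # sample, each pair contributing its original and its re-injection
  expect_identical(s$batch_replicate_pairs, 70L)
  expect_identical(s$batch_replicate_measurements, 140L)
  expect_identical(s$distinct_batch_replicated, 70L)
  # one short replicate per row from the second row onward
  expect_identical(s$short_replicate_pairs, (8L - 1L) * 15L)
  expect_identical(s$pooled_qc, 8L * 15L)
  expect_identical(s$conditioning_qc, 3L * 15L)
  expect_identical(s$n_entries, 15L * (3L + 88L))
})

test_that("a single batch has no batch replicates and a per-row short replicate", {
  sheet <- generate_design(design_config(n_batches = 1, seed = 2))
  s <- summarize_design(sheet)
  expect_identical(s$batch_replicate_pairs, 0L)
  expect_identical(s$short_replicate_pairs, 7L)
  per_row <- table(sheet$row[sheet$sample_type == "shortReplicate"])
  expect_true(all(per_row == 1))
  expect_identical(sort(as.integer(names(per_row))), 2:8)
})

test_that("replicate-count invariants hold across configurations", {
  for (cfg in list(design_config(2, rows_per_batch = 3, row_size = 5,
                                 n_batch_replicates = 2, seed = 1),
                   design_config(4, rows_per_batch = 5, row_size = 7,
                                 n_batch_replicates = 3, seed = 9),
                   design_config(6, seed = 5))) {
    s <- summarize_design(generate_design(cfg))
    expect_identical(s$batch_replicate_pairs,
                     as.integer(cfg$n_batch_replicates * (cfg$n_batches - 1)))
    expect_identical(s$short_replicate_pairs,
                     as.integer((cfg$rows_per_batch - 1) * cfg$n_batches))
  }
})

test_that("sheets are reproducible by seed and count-stable across seeds", {
  cfg1 <- design_config(4, seed = 11)
  expect_identical(generate_design(cfg1), generate_design(cfg1))
  s1 <- summarize_design(generate_design(design_config(4, seed = 11)))
  s2 <- summarize_design(generate_design(design_config(4, seed = 12)))
  expect_false(identical(generate_design(design_config(4, seed = 11)),
                         generate_design(design_config(4, seed = 12))))
  for (f in c("short_replicate_pairs", "batch_replicate_pairs", "pooled_qc",
              "individuals", "n_entries"))
    expect_identical(s1[[f]], s2[[f]])
})

test_that("sheet structure honours the replicate-placement rules", {
  sheet <- generate_design(design_config(5, seed = 3))
  expect_identical(as.integer(sheet$run_index), seq_len(nrow(sheet)))
  for (b in unique(sheet$batch)) {
    sb <- sheet[sheet$batch == b, ]
    sh <- sb[sb$sample_type == "shortReplicate", ]
    expect_false(anyDuplicated(sh$replicate_group) > 0)
    ind <- sb[sb$sample_type == "individual", ]
    for (j in seq_len(nrow(sh))) {
      src <- ind[ind$replicate_group == sh$replicate_group[j], ]
      expect_identical(nrow(src), 1L)
      expect_lt(src$row, sh$row[j])
    }
    br <- sb[sb$sample_type == "batchReplicate", ]
    if (b == 1) expect_identical(nrow(br), 0L)
    else {
      prev_ind <- sheet[sheet$batch == b - 1 &
                          sheet$sample_type == "individual", ]
      expect_true(all(br$replicate_group %in% prev_ind$replicate_group))
      # contiguous block at the start of the grid, right after conditioning
      expect_true(all(br$row == 1 & br$column == seq_len(nrow(br))))
    }
    qc <- sb[sb$sample_type %in% c("pooledQC", "conditioningQC"), ]
    expect_true(all(qc$replicate_group == "QC"))
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(design_config(2, rows_per_batch = 1, row_size = 3,
                             n_batch_replicates = 2),
               "individual slots|non-QC slots")
  expect_error(design_config(0), "n_batches")
  expect_error(design_config(2, row_size = 1), "row_size")
})

test_that("design CSV round-trips and rejects malformed files", {
  sheet <- generate_design(design_config(3, seed = 13))
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(sheet, path)
  back <- read_design_csv(path)
  expect_identical(as.data.frame(back)[, 1:7], as.data.frame(sheet)[, 1:7])

  # duplicated run index must be reported
  df <- utils::read.csv(path)
  df$run_index[2] <- df$run_index[1]
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(read_design_csv(bad), "run_index")

  # header-only file parses to an empty sheet
  writeLines("batch,run_index,row,column,sample_id,sample_type,replicate_group",
             hdr <- withr::local_tempfile(fileext = ".csv"))
  empty <- read_design_csv(hdr)
  expect_identical(nrow(empty), 0L)
  s <- summarize_design(empty)
  expect_identical(s$short_replicate_pairs, 0L)
  expect_identical(s$batch_replicate_pairs, 0L)
  expect_identical(s$pooled_qc, 0L)
})

test_that("stratified batch-replicate selection draws from both halves", {
  cfg <- design_config(4, stratify_batch_replicates = TRUE, seed = 21)
  sheet <- generate_design(cfg)
  for (b in 2:4) {
    br <- sheet[sheet$batch == b & sheet$sample_type == "batchReplicate", ]
    prev <- sheet[sheet$batch == b - 1 & sheet$sample_type == "individual", ]
    rows <- prev$row[match(br$replicate_group, prev$replicate_group)]
    expect_true(any(rows <= 4) && any(rows >= 5))
  }
})
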