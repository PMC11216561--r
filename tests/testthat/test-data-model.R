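test_that("predictions CSV rows are grouped by case and vessel in order", {
  df <- tibble::tibble(
    case_id = rep(c("a", "b"), each = 3),
    vessel = c(rep("Arterial", 3), rep("venous", 3)),
    predicted_icp = c(21, 22, 23, 31, 32, 33),
    eye = "left", iop_level = 1:6)
  recs <- read_predictions_csv(write_temp_predictions(df))
  expect_length(recs, 2)
  expect_equal(recs[[1]]$case_id, "a")
  expect_equal(recs[[1]]$vessel, "arterial")  # case-insensitive on read
  expect_equal(recs[[1]]$samples, c(21, 22, 23))
  expect_equal(recs[[2]]$n, 3)
})

test_that("predictions CSV errors are classed and informative", {
  df <- tibble::tibble(case_id = "a", predicted_icp = 1:3)
  expect_error(read_predictions_csv(write_temp_predictions(df)),
               "vessel", class = "icpdx_schema_error")
  df2 <- tibble::tibble(case_id = "a", vessel = "arterial",
                        predicted_icp = c("21", "oops", "23"))
  expect_error(read_predictions_csv(write_temp_predictions(df2)),
               "row", class = "icpdx_parse_error")
  df3 <- tibble::tibble(case_id = "a", vessel = "arterial", predicted_icp = c(1, 2))
  expect_error(read_predictions_csv(write_temp_predictions(df3)),
               class = "icpdx_validation_error")
  expect_error(read_predictions_csv(file.path(tempdir(), "nope.csv")),
               class = "icpdx_io_error")
})

test_that("metadata CSV reads, validates and warns on degenerate input", {
  md <- read_metadata_csv(write_temp_metadata(tibble::tibble(
    case_id = "case_1", measured_icp = 22, laterality = 2,
    n_iop_levels = 14, subset = "hold_out")))
  expect_length(md, 1)
  expect_equal(md[[1]]$measured_icp, 22)
  expect_equal(md[[1]]$laterality, 2L)
  expect_equal(md[[1]]$n_iop_levels, 14L)

  bad_lat <- tibble::tibble(case_id = "x", measured_icp = 20, laterality = 3,
                            n_iop_levels = 10, subset = "hold_out")
  expect_error(read_metadata_csv(write_temp_metadata(bad_lat)),
               class = "icpdx_validation_error")

  dup <- small_metadata_df(c("a", "a"))
  expect_error(read_metadata_csv(write_temp_metadata(dup)),
               class = "icpdx_validation_error")

  empty <- small_metadata_df()[0, ]
  expect_warning(md0 <- read_metadata_csv(write_temp_metadata(empty)), "no rows")
  expect_length(md0, 0)
})

test_that("record and metadata constructors enforce their invariants", {
  expect_error(case_metadata("x", -1, 1, 10), class = "icpdx_validation_error")
  expect_error(case_metadata("x", 20, 1, 0), class = "icpdx_validation_error")
  expect_error(case_metadata("x", 20, 1, 10, subset = "training"),
               class = "icpdx_validation_error")
  expect_error(case_record("x", "capillary", 1:5), class = "icpdx_validation_error")
  expect_error(case_record("x", "arterial", c(1, 2, NA)),
               class = "icpdx_validation_error")
  meta <- case_metadata("x", 20, 2, 10)
  rec <- case_record("x", "ARTERIAL", 1:5, meta)
  expect_s3_class(rec, "icpdx_case_record")
  expect_equal(rec$n, 5)
})

test_that("attach_metadata joins by case id and errors on a missing case", {
  recs <- list(case_record("a", "arterial", 1:4), case_record("b", "venous", 1:4))
  md <- read_metadata_csv(write_temp_metadata(small_metadata_df()))
  joined <- attach_metadata(recs, md)
  expect_equal(joined[[2]]$meta$subset, "cautionary")
  expect_error(attach_metadata(list(case_record("zz", "venous", 1:4)), md),
               class = "icpdx_join_error")
})

test_that("the packaged cohort fixture carries the reference values", {
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 18)
  expect_equal(nrow(unique(t2[c("case_id", "vessel")])), 18)
  expect_equal(t2$median[t2$case_id == "case_9" & t2$vessel == "arterial"], 45.09)
  expect_equal(t2$di_icp[t2$case_id == "case_8" & t2$vessel == "venous"], 24.46)
  # independently keyed spot sums of the data-point counts
  expect_equal(sum(t2$n[t2$vessel == "venous"]), 12288)
  expect_equal(sum(t2$n[t2$vessel == "arterial"]), 8623)
  expect_setequal(unique(t2$subset[t2$case_id %in% c("case_8", "case_9")]),
                  "cautionary")
})

test_that("the harmonics fixture has one row per parameter, site and group", {
  t1 <- load_table1_fixture()
  expect_equal(nrow(t1), 20)
  expect_equal(t1$median[t1$parameter == "hrw_a" & t1$site == "vein" &
                           t1$group == "hold_out"], 7.028)
  expect_equal(t1$iqr[t1$parameter == "hrw_a" & t1$site == "vein" &
                        t1$group == "hold_out"], 6.123)
})

test_that("diagnostics CSV round-trips at full precision", {
  t2 <- load_table2_fixture()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "diag.csv")
  write_diagnostics_csv(t2, path)
  expect_equal(length(readLines(path)), 19)  # header + 18 rows
  back <- read_diagnostics_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(t2))

  write_diagnostics_csv(t2[0, ], file.path(dir, "empty.csv"))
  expect_equal(length(readLines(file.path(dir, "empty.csv"))), 1)
  expect_error(write_diagnostics_csv(t2, file.path(dir, "no/such/dir/x.csv")),
               class = "icpdx_io_error")
})

test_that("pressure unit conversion is exact and involutive", {
  expect_equal(mmhg_to_cmh2o(1), 1.35951)
  expect_equal(cmh2o_to_mmhg(mmhg_to_cmh2o(c(7, 15, 22))), c(7, 15, 22))
})
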