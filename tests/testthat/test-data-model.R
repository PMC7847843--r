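test_that("Mosteller BSA matches hand-computed values and is monotone", {
  expect_equal(compute_bsa(90, 12), sqrt(90 * 12 / 3600))
  expect_equal(compute_bsa(90, 12), 0.5477, tolerance = 1e-4)
  expect_equal(compute_bsa(44, 2.5), 0.1748, tolerance = 1e-3)
  expect_equal(compute_bsa(60, 60), 1.0)
  ## strictly increasing in each argument
  h <- seq(50, 150, by = 10)
  expect_true(all(diff(compute_bsa(h, 12)) > 0))
  expect_true(all(diff(compute_bsa(90, seq(3, 50, by = 2))) > 0))
  expect_error(compute_bsa(-1, 12), "positive")
})

test_that("kidney-function ratio is eGFR/120", {
  expect_equal(compute_kf(120), 1.0)
  expect_equal(compute_kf(60), 0.5)
  expect_equal(compute_kf(110.85), 0.9238, tolerance = 1e-4)
  expect_error(compute_kf(0), "positive")
})

test_that("renal classification partitions eGFR with closed lower bounds", {
  expect_equal(as.character(classify_renal(120)), "elevated")
  expect_equal(as.character(classify_renal(90)), "normal")
  expect_equal(as.character(classify_renal(14.61)), "severe")
  expect_equal(as.character(classify_renal(c(29.9, 30, 59.9, 60, 89.9))),
               c("severe", "moderate", "moderate", "mild", "mild"))
  ## every positive value maps to exactly one class, monotone in egfr
  grid <- seq(1, 200, by = 0.5)
  cls <- classify_renal(grid)
  expect_true(!anyNA(cls))
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("pk_dataset validates structure and flags BLQ", {
  ds <- tiny_dataset(conc = c(4, 2, 1, 0.05), times = c(0.5, 1, 2, 6))
  expect_s3_class(ds, "pk_dataset")
  expect_equal(sum(ds$observations$below_loq), 1L)
  ## observation before any dose rejected
  subjects <- ds$subjects[, c("id", "wt", "height", "age", "sex", "scr", "egfr")]
  expect_error(
    pk_dataset(subjects, data.frame(id = "S1", time = 2, amount = 60,
                                    duration = 1),
               data.frame(id = "S1", time = 1, conc = 1)),
    "before any dose")
  expect_error(
    pk_dataset(subjects, data.frame(id = "S1", time = 0, amount = 60,
                                    duration = 0),
               data.frame(id = "S1", time = 1, conc = 1)),
    "duration")
})

test_that("NONMEM-dialect reader handles doses, observations and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,AMT,DUR,DV,EVID,MDV,WT,HT,AGE,SEX,SCR,EGFR",
    "1,0,60,1,,1,1,12,90,2.5,M,26,110",
    "1,1,0,,4.2,0,0,12,90,2.5,M,26,110"), path)
  ds <- read_pkdata(path)
  expect_equal(nrow(ds$subjects), 1L)
  expect_equal(nrow(ds$doses), 1L)
  expect_equal(nrow(ds$observations), 1L)
  expect_equal(ds$observations$conc, 4.2)
  expect_equal(ds$doses$duration, 1)

  ## RATE accepted in place of DUR: duration = AMT/RATE
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,AMT,RATE,DV,EVID,MDV,WT,HT,AGE,SEX,SCR,EGFR",
    "1,0,60,60,,1,1,12,90,2.5,M,26,110",
    "1,1,0,,4.2,0,0,12,90,2.5,M,26,110"), path2)
  expect_equal(read_pkdata(path2)$doses$duration, 1)

  ## missing mandatory column named in the error
  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,DUR,EVID,WT,HT,AGE,SEX,SCR,EGFR",
               "1,0,60,1,1,12,90,2.5,M,26,110"), path3)
  expect_error(read_pkdata(path3), "DV")

  ## non-numeric cell reported with row number
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ID,TIME,AMT,DUR,DV,EVID,MDV,WT,HT,AGE,SEX,SCR,EGFR",
    "1,0,60,1,,1,1,12,90,2.5,M,26,110",
    "1,oops,0,,4.2,0,0,12,90,2.5,M,26,110"), path4)
  expect_error(read_pkdata(path4), "TIME.*row 2")
})

test_that("write/read round-trip is bit-exact for numeric fields", {
  res <- small_study(n_subjects = 8, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pkdata(res$dataset, path)
  back <- read_pkdata(path)
  expect_identical(back$observations$conc, res$dataset$observations$conc)
  expect_identical(back$observations$time, res$dataset$observations$time)
  expect_identical(back$doses$amount, res$dataset$doses$amount)
  expect_identical(back$subjects$wt, res$dataset$subjects$wt)
  expect_identical(back$subjects$egfr, res$dataset$subjects$egfr)
})

test_that("manifest reports counts and covariate summaries", {
  res <- small_study(n_subjects = 10, seed = 3)
  man <- dataset_manifest(res$dataset)
  expect_equal(man$n_subjects, 10)
  expect_equal(man$n_observations, 30)
  expect_equal(man$covariates$wt$median,
               stats::median(res$dataset$subjects$wt))
  path <- withr::local_tempfile(fileext = ".json")
  dataset_manifest(res$dataset, path)
  expect_true(file.exists(path))
  expect_equal(jsonlite::read_json(path)$n_subjects, 10)
})
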