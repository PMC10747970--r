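test_that("read_paired_csv parses valid files and preserves row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,parameter,trial,side,system,value",
    "A,cadence,1,na,reference,90",
    "A,cadence,2,na,reference,92",
    "A,cadence,3,na,reference,94",
    "A,cadence,1,na,test,95",
    "A,cadence,2,na,test,96",
    "A,cadence,3,na,test,97"), path)
  rec <- read_paired_csv(path)
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$value, c(90, 92, 94, 95, 96, 97))
  expect_equal(rec$trial, c(1L, 2L, 3L, 1L, 2L, 3L))
})

test_that("read_paired_csv handles empty files, schema mapping, and errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("subject_id,parameter,trial,side,system,value", path)
  expect_equal(nrow(read_paired_csv(path)), 0L)

  # remapped column names via schema
  writeLines(c("id,param,sys,v", "A,speed,reference,0.6", "A,speed,test,0.65"), path)
  rec <- read_paired_csv(path, schema = c(subject_id = "id", parameter = "param",
                                          system = "sys", value = "v"))
  expect_equal(rec$value, c(0.6, 0.65))
  expect_equal(rec$trial, c(1L, 1L))

  # non-numeric value cites the offending row
  writeLines(c("subject_id,parameter,system,value",
               "A,speed,reference,0.6", "A,speed,test,0.65",
               "B,speed,reference,0.7", "B,speed,test,abc"), path)
  expect_error(read_paired_csv(path), "row.*4", class = "gaitagree_error_parse")

  # missing column named in the error
  writeLines(c("subject_id,parameter,value", "A,speed,0.6"), path)
  expect_error(read_paired_csv(path), "system", class = "gaitagree_error_schema")

  # unknown system label
  writeLines(c("subject_id,parameter,system,value", "A,speed,gold,0.6"), path)
  expect_error(read_paired_csv(path), "gold", class = "gaitagree_error_value")
})

test_that("average_trials averages over trials and sides per subject-system", {
  rec <- bind_records <- dplyr::bind_rows(
    make_records("A", "cadence", "reference", c(90, 92, 94), trial = 1:3),
    make_records(c("A", "A"), "cadence", "test", c(95, 97), trial = 1:2),
    make_records(c("B", "B"), "cadence", "reference", c(80, 84), trial = 1:2),
    make_records("B", "cadence", "test", 85),
    make_records("C", "cadence", "reference", 100),
    make_records("C", "cadence", "test", 101))
  paired <- average_trials(rec)
  expect_equal(nrow(paired), 3L)
  expect_equal(paired$reference[paired$subject_id == "A"], 92)  # mean of 3
  expect_equal(paired$test[paired$subject_id == "A"], 96)
  expect_equal(paired$reference[paired$subject_id == "B"], 82)
})

test_that("subjects under only one system are dropped with a warning", {
  rec <- dplyr::bind_rows(
    make_records(c("A", "B", "C", "D"), "cadence", "reference", c(90, 91, 92, 93)),
    make_records(c("A", "B", "C"), "cadence", "test", c(95, 96, 97)))
  expect_warning(paired <- average_trials(rec), "D/cadence")
  expect_equal(sort(paired$subject_id), c("A", "B", "C"))
})

test_that("a fully crossed design yields one complete series per parameter", {
  cfg <- synthetic_config(n_subjects = 15, n_trials = 4, seed = 301)
  paired <- average_trials(generate_gait(cfg))
  counts <- dplyr::count(paired, parameter)
  expect_equal(nrow(counts), 6L)
  expect_true(all(counts$n == 15L))
})

test_that("averaging is idempotent and invariant to trial order", {
  cfg <- synthetic_config(n_subjects = 6, n_trials = 3, seed = 88)
  rec <- generate_gait(cfg)
  paired <- average_trials(rec)

  # idempotent: feeding averaged values back (one trial each) changes nothing
  reavg <- average_trials(dplyr::bind_rows(
    make_records(paired$subject_id, paired$parameter, "reference", paired$reference),
    make_records(paired$subject_id, paired$parameter, "test", paired$test)))
  expect_equal(reavg, paired)

  # permutation over rows
  shuffled <- rec[withr::with_seed(1, sample(nrow(rec))), ]
  expect_equal(average_trials(shuffled), paired)
})

test_that("read -> write -> read round trip preserves values to full precision", {
  cfg <- synthetic_config(n_subjects = 5, n_trials = 2, seed = 17)
  rec <- generate_gait(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(rec, path)
  back <- read_paired_csv(path)
  expect_equal(back$value, rec$value, tolerance = 0)
  expect_equal(back$subject_id, rec$subject_id)
})
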