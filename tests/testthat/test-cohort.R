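test_that("cohort CSV round trip is byte-identical and validates on read", {
  co <- make_cohort(list(c(0, 1, 0), c(1, 0, 1)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f1)
  back <- read_cohort(f1)
  expect_s3_class(back, "hf_cohort")
  expect_equal(nrow(back), 6)
  expect_equal(back$hf[1:3], c(0, 1, 0))
  write_cohort(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("schema remapping and error reporting work", {
  co <- make_cohort(list(c(0, 1)))
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- tibble::as_tibble(co)
  names(tab)[names(tab) == "hf"] <- "heart_failure"
  readr::write_csv(tab, f)
  expect_error(read_cohort(f), class = "hftraj_schema_error")
  back <- read_cohort(f, schema = c(hf = "heart_failure"))
  expect_equal(back$hf, c(0, 1))
  expect_error(read_cohort("no/such/file.csv"), class = "hftraj_io_error")
})

test_that("cohort invariants are enforced with row-level messages", {
  co <- tibble::as_tibble(make_cohort(list(c(0, 1, 0))))
  bad <- co; bad$sex_f[2] <- 1
  expect_error(as_cohort(bad), "one-hot", class = "hftraj_validation_error")
  bad <- co; bad$lesion_other <- 0
  expect_error(as_cohort(bad), "lesion", class = "hftraj_validation_error")
  bad <- co; bad$hf[1] <- 2
  expect_error(as_cohort(bad), "non-binary", class = "hftraj_validation_error")
  bad <- co; bad$age[3] <- 99
  expect_error(as_cohort(bad), "0.5", class = "hftraj_validation_error")
  bad <- co; bad$step <- c(0, 2, 3)
  expect_error(as_cohort(bad), "consecutive", class = "hftraj_validation_error")
  bad <- co[1, ]
  expect_error(as_cohort(bad), "fewer than 2", class = "hftraj_validation_error")
})

test_that("writing an empty cohort produces a header-only file", {
  co <- make_cohort(list(c(0, 1)))
  empty <- tibble::as_tibble(co)[0, ]
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(empty, f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_match(lines, "^patient_id,step,age")
})

test_that("age-window restriction truncates, re-bases and drops correctly", {
  # 7 steps observed from age 38: ages 38.0 .. 41.0
  tl <- make_timeline(rep(0:1, length.out = 7), age_start = 38)
  young <- make_timeline(c(0, 1, 0), patient_id = "P2", age_start = 30)
  old <- make_timeline(c(1, 0, 1), patient_id = "P3", age_start = 50)
  co <- as_cohort(dplyr::bind_rows(tl, young, old))

  out <- restrict_to_age_window(co, min_age = 40)
  p1 <- out[out$patient_id == "P1", ]
  expect_equal(nrow(p1), 3)
  expect_equal(p1$age, c(40, 40.5, 41))
  expect_equal(p1$step, 0:2)
  expect_false("P2" %in% out$patient_id)
  p3 <- out[out$patient_id == "P3", ]
  expect_equal(p3$hf, c(1, 0, 1))
  expect_equal(p3$step, 0:2)
  # idempotence
  expect_equal(restrict_to_age_window(out, 40), out)
  # empty output allowed
  expect_equal(nrow(restrict_to_age_window(co, min_age = 99)), 0)
})

test_that("encode_inputs yields 20-wide inputs and next-step targets", {
  tl <- make_timeline(c(1, 0, 1), cm = list(cm_sepsis = c(0, 0, 1)))
  enc <- encode_inputs(tl)
  expect_equal(dim(enc$inputs), c(2, 20))
  expect_equal(unname(enc$inputs[, "hf"]), c(1, 0))
  expect_equal(enc$targets, c(0, 1))

  # multi-task targets carry the acute co-morbidities at i + 1:
  # sepsis onset at (0-based) step 2 appears in the target of pair i = 1
  enc2 <- encode_inputs(tl, include_cm_targets = TRUE)
  expect_equal(dim(enc2$targets), c(2, 4))
  expect_equal(unname(enc2$targets[, "cm_sepsis"]), c(0, 1))
  expect_equal(unname(enc2$targets[, "hf"]), c(0, 1))

  # all-zero covariates: input is [0 x 19, hf]
  zero_tl <- make_timeline(c(1, 0))
  zero_tl[covariate_columns()] <- 0
  enc3 <- encode_inputs(zero_tl)
  expect_equal(unname(enc3$inputs[1, ]), c(rep(0, 19), 1))
  expect_equal(enc3$targets, 0)

  # age scaling is part of the encoding contract
  enc4 <- encode_inputs(tl, age_scale = 0.01)
  expect_equal(unname(enc4$inputs[, "age"]), c(0.40, 0.405))

  expect_error(encode_inputs(make_timeline(c(0, 1))[1, ]),
               class = "hftraj_contract_error")
})

test_that("encode_inputs output count equals timeline length - 1", {
  for (T_len in c(2, 3, 7, 12)) {
    tl <- make_timeline(rep_len(c(0, 1), T_len))
    expect_equal(nrow(encode_inputs(tl)$inputs), T_len - 1)
  }
})
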