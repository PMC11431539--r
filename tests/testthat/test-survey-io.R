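plain <- function(d) {
  d <- as.data.frame(d)
  attributes(d) <- attributes(d)[c("names", "row.names", "class")]
  d
}

test_that("a survey round-trips through CSV field-for-field", {
  d <- survey_dataset(records_df(
    make_record(),
    make_record(age = NA, gender = NA, pain = 7L),
    make_record(q1_surgery = "no", q2_postop_care = NA, infection = NA,
                complication = NA, protocol = NA, innovation = NA, pain = NA),
    make_record(residence = NA, education = NA, q3_overall = NA),
    make_record(year = 2023, ward = "ent", age = 12, pain = 10L),
    make_record(q2_postop_care = 1L, q3_overall = 5L),
    make_record(gender = "male", residence = "urban"),
    make_record(education = "university", infection = "yes"),
    make_record(complication = "yes", protocol = "personalized"),
    make_record(innovation = "yes", age = 96)
  ))
  f <- withr::local_tempfile(fileext = ".csv")
  write_survey(d, f)
  back <- read_survey(f)
  expect_equal(plain(back), plain(d))
})

test_that("degenerate datasets round-trip: all-missing optional fields, zero records", {
  f <- withr::local_tempfile(fileext = ".csv")
  d <- survey_dataset(data.frame(year = c(2020, 2021), ward = "a"))
  write_survey(d, f)
  expect_equal(plain(read_survey(f)), plain(d))

  empty <- survey_dataset(data.frame(year = integer(0), ward = character(0)))
  write_survey(empty, f)
  back <- read_survey(f)
  expect_s3_class(back, "survey_dataset")
  expect_identical(nrow(back), 0L)
})

test_that("read_survey maps rows to records and flags unparseable cells", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(survey_fields(), collapse = ","),
    "2019,a,50,male,urban,primary,yes,4,5,no,no,standard,no,3",
    "2020,b,61,female,rural,secondary,no,,4,,,,,",
    "2021,c,44,male,urban,university,yes,5,5,no,no,standard,no,abc"
  ), f)
  expect_warning(d <- read_survey(f), class = "postopsat_parse_warning")
  expect_identical(nrow(d), 3L)
  expect_true(is.na(d$pain[3]))        # unparseable cell became missing
  expect_identical(d$q2_postop_care[1], 4)
  expect_true(is.na(d$q2_postop_care[2]))
})

test_that("missing mandatory columns raise a schema error naming them", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,age", "2020,50"), f)
  expect_error(read_survey(f), "ward", class = "postopsat_schema_error")
})

test_that("out-of-range and inconsistent-level cells are nulled with a warning", {
  expect_warning(
    d <- survey_dataset(records_df(
      make_record(pain = 15L), make_record(q2_postop_care = 9L),
      make_record(age = 300), make_record(gender = "other")
    )),
    class = "postopsat_parse_warning"
  )
  expect_true(is.na(d$pain[1]))
  expect_true(is.na(d$q2_postop_care[2]))
  expect_true(is.na(d$age[3]))
  expect_true(is.na(d$gender[4]))
})

test_that("missingness_fraction counts missing in-scope fields", {
  fields <- missingness_fields()
  expect_identical(missingness_fraction(make_record(), fields), 0)
  r3 <- make_record(age = NA, gender = NA, pain = NA)
  expect_equal(missingness_fraction(r3, fields), 3 / 12)
  all_miss <- as.list(stats::setNames(rep(NA, 12), fields))
  expect_identical(missingness_fraction(all_miss, fields), 1)
  expect_equal(missingness_fraction(r3, c("age", "year")), 0.5)
  expect_error(missingness_fraction(make_record(), character(0)),
               class = "postopsat_argument_error")
})

test_that("apply_exclusion implements the strict over-20% rule", {
  # exactly 20% missing (2 of 10 in-scope fields) is retained
  fields10 <- setdiff(missingness_fields(), c("education", "q3_overall"))
  boundary <- make_record(age = NA, gender = NA)
  over <- make_record(age = NA, gender = NA, pain = NA)
  d <- survey_dataset(records_df(boundary, over, make_record()))
  res <- apply_exclusion(d, threshold = 0.20, fields = fields10)
  expect_identical(nrow(res$retained), 2L)
  expect_identical(nrow(res$excluded), 1L)
  expect_equal(missingness_fraction(boundary, fields10), 0.20)

  # threshold 0 keeps only fully complete records
  res0 <- apply_exclusion(d, threshold = 0, fields = fields10)
  expect_identical(nrow(res0$retained), 1L)
})

test_that("exclusion partitions the dataset and is monotone in the threshold", {
  set.seed(42)
  base <- do.call(records_df, replicate(60, make_record(), simplify = FALSE))
  fields <- missingness_fields()
  for (i in seq_len(nrow(base))) {
    k <- sample(0:6, 1)
    if (k > 0) base[i, sample(fields, k)] <- NA
  }
  d <- survey_dataset(base)
  prev_retained <- -1L
  for (thr in c(0, 0.1, 0.2, 0.35, 0.5, 1)) {
    res <- apply_exclusion(d, thr, conditional = FALSE)
    expect_identical(nrow(res$retained) + nrow(res$excluded), nrow(d))
    expect_true(nrow(res$retained) >= prev_retained)
    prev_retained <- nrow(res$retained)
    if (nrow(res$retained)) {
      expect_true(all(missingness_fraction(res$retained, fields) <= thr))
    }
    if (nrow(res$excluded)) {
      expect_true(all(missingness_fraction(res$excluded, fields) > thr))
    }
  }
})

test_that("non-operated records are judged on their applicable fields only", {
  skipper <- make_record(q1_surgery = "no", q2_postop_care = NA,
                         infection = NA, complication = NA, protocol = NA,
                         innovation = NA, pain = NA)
  d <- survey_dataset(records_df(skipper))
  # 6 of 12 fields blank, but all of them structurally inapplicable
  expect_identical(nrow(apply_exclusion(d)$retained), 1L)
  expect_identical(nrow(apply_exclusion(d, conditional = FALSE)$retained), 0L)
})

test_that("consistency_check flags answers that contradict the surgery item", {
  expect_identical(
    consistency_check(make_record(q1_surgery = "no", q2_postop_care = 5L,
                                  infection = NA, complication = NA,
                                  protocol = NA, innovation = NA, pain = NA)),
    "Q2_WITHOUT_SURGERY")
  expect_identical(consistency_check(make_record(q2_postop_care = 4L)),
                   character(0))
  expect_identical(
    consistency_check(make_record(q1_surgery = "no", q2_postop_care = NA,
                                  infection = NA, complication = NA,
                                  protocol = NA, innovation = NA, pain = 6L)),
    "CLINICAL_WITHOUT_SURGERY")
  flags <- consistency_flags(survey_dataset(records_df(
    make_record(), make_record(q1_surgery = "no"))))
  expect_identical(flags, c(FALSE, TRUE))
})
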