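test_that("age and pain factors follow their published linear forms", {
  expect_identical(age_factor(0), 1.0)
  expect_equal(age_factor(50), 1.5)
  expect_equal(age_factor(96), 1.96)   # oldest respondent in the study design
  expect_error(age_factor(-1), class = "postopsat_domain_error")

  expect_identical(pain_factor(0), 1.0)
  expect_equal(pain_factor(10), 2.0)
  expect_equal(pain_factor(3), 1.3)
  expect_error(pain_factor(11), class = "postopsat_domain_error")
  expect_error(pain_factor(-0.5), class = "postopsat_domain_error")
})

test_that("categorical factors return the published constants", {
  expect_identical(categorical_factor("complication", "yes"), 2.0)
  expect_identical(categorical_factor("protocol", "personalized"), 0.8)
  expect_identical(categorical_factor("residence", "urban"), 1.3)
  expect_identical(categorical_factor("gender", "male"), 1.2)
  expect_identical(categorical_factor("infection", "yes"), 1.5)
  expect_identical(categorical_factor("innovation", "yes"), 0.9)
  expect_error(categorical_factor("gender", NA),
               class = "postopsat_missing_input")
  expect_error(categorical_factor("protocol", "bespoke"),
               class = "postopsat_domain_error")
})

test_that("total_score multiplies the eight factors", {
  unit <- make_record(age = 0, pain = 0L)
  s <- total_score(unit)
  expect_equal(s$total, 1.0, tolerance = 1e-12)
  expect_identical(s$category, "high")

  s2 <- total_score(make_record(gender = "male", age = 50,
                                residence = "urban", infection = "yes",
                                pain = 5L))
  expect_equal(s2$total, 5.2650, tolerance = 1e-12)
  expect_identical(s2$category, "low")

  s3 <- total_score(make_record(age = 30, protocol = "personalized",
                                innovation = "yes", pain = 2L))
  expect_equal(s3$total, 1.1232, tolerance = 1e-12)
  expect_identical(s3$category, "high")

  expect_error(total_score(make_record(q1_surgery = "no")),
               class = "postopsat_domain_error")
  expect_error(total_score(make_record(pain = NA)),
               class = "postopsat_missing_input")
  # neutral policy substitutes the unit factor for the missing input
  expect_equal(total_score(make_record(pain = NA), policy = "neutral")$total,
               total_score(make_record(pain = 0L))$total)
})

test_that("category bands follow the printed inequalities at their boundaries", {
  expect_identical(categorize(1.5), "high")
  expect_identical(categorize(3.0), "moderate")
  expect_identical(categorize(3.0000001), "low")
  expect_identical(categorize(1.5000001), "moderate")
  expect_identical(categorize(0.1), "high")
  expect_error(categorize(0), class = "postopsat_domain_error")
})

test_that("every total decomposes into the eight factor functions and responds monotonically", {
  set.seed(7)
  d <- random_records(1000)
  scores <- score_dataset(survey_dataset(d))
  expect_identical(nrow(scores), 1000L)
  w <- factor_weights()
  for (i in seq_len(nrow(d))) {
    expected <- categorical_factor("gender", d$gender[i], w) *
      age_factor(d$age[i], w) *
      categorical_factor("residence", d$residence[i], w) *
      categorical_factor("infection", d$infection[i], w) *
      categorical_factor("complication", d$complication[i], w) *
      categorical_factor("protocol", d$protocol[i], w) *
      categorical_factor("innovation", d$innovation[i], w) *
      pain_factor(d$pain[i], w)
    expect_equal(scores$total[i], expected, tolerance = 1e-12)
    expect_identical(scores$category[i], categorize(expected, w))
  }

  # monotonicity and exact factor ratios, all else equal
  base <- make_record(age = 40, pain = 4L)
  t0 <- total_score(base)$total
  expect_true(total_score(make_record(age = 41, pain = 4L))$total > t0)
  expect_true(total_score(make_record(age = 40, pain = 5L))$total > t0)
  expect_equal(total_score(modifyList(base, list(infection = "yes")))$total,
               1.5 * t0, tolerance = 1e-12)
  expect_equal(total_score(modifyList(base, list(complication = "yes")))$total,
               2.0 * t0, tolerance = 1e-12)
  expect_equal(
    total_score(modifyList(base, list(protocol = "personalized")))$total,
    0.8 * t0, tolerance = 1e-12)
  expect_equal(total_score(modifyList(base, list(innovation = "yes")))$total,
               0.9 * t0, tolerance = 1e-12)
})

test_that("score_dataset skips unscorable records with explicit reasons", {
  d <- survey_dataset(records_df(
    make_record(), make_record(age = 61), make_record(age = 35)))
  expect_identical(nrow(score_dataset(d)), 3L)

  d2 <- survey_dataset(records_df(
    make_record(), make_record(q1_surgery = "no", q2_postop_care = NA),
    make_record()))
  s2 <- score_dataset(d2)
  expect_identical(nrow(s2), 2L)
  expect_identical(attr(s2, "skipped")$reason, "not operated")

  d3 <- survey_dataset(records_df(
    make_record(), make_record(q1_surgery = "no", q2_postop_care = NA),
    make_record(pain = NA)))
  s3 <- score_dataset(d3)
  expect_identical(nrow(s3), 1L)
  expect_setequal(attr(s3, "skipped")$reason,
                  c("not operated", "missing: pain"))
  # neutral policy scores the missing-pain record instead
  expect_identical(nrow(score_dataset(d3, policy = "neutral")), 2L)
})

test_that("weights are validated and configurable", {
  expect_error(factor_weights(complication_yes = -1),
               class = "postopsat_config_error")
  expect_error(factor_weights(high_threshold = 3, low_threshold = 2),
               class = "postopsat_config_error")
  w <- factor_weights(gender_male = 1.0)
  expect_identical(categorical_factor("gender", "male", w), 1.0)

  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"weights": {"complication_yes": 3.5}}', f)
  expect_identical(read_weights(f)$complication_yes, 3.5)
  writeLines('{"weights": {"not_a_field": 1}}', f)
  expect_error(read_weights(f), class = "postopsat_config_error")
})
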