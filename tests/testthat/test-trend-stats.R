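test_that("likert_summary reports per-cell n, mean and sd", {
  d <- survey_dataset(records_df(
    make_record(ward = "a", year = 2019, q2_postop_care = 5L),
    make_record(ward = "a", year = 2019, q2_postop_care = 5L),
    make_record(ward = "a", year = 2019, q2_postop_care = 4L),
    make_record(ward = "b", year = 2019, q2_postop_care = 3L),
    make_record(ward = "b", year = 2020, q2_postop_care = NA)
  ))
  s <- likert_summary(d, "q2_postop_care")
  a <- s[s$ward == "a", ]
  expect_identical(a$n, 3L)
  expect_equal(a$mean, 14 / 3)
  b <- s[s$ward == "b" & s$year == 2019, ]
  expect_identical(b$n, 1L)
  expect_equal(b$mean, 3)
  expect_identical(b$sd, 0)           # single response: no observed spread
  expect_false(any(s$year == 2020))   # all-missing cell omitted
  expect_identical(nrow(attr(s, "omitted")), 1L)
  expect_error(likert_summary(d, "q9"), class = "postopsat_argument_error")
})

test_that("one-way ANOVA matches the definitional sum-of-squares oracle", {
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  expect_error(anova_oneway(list(c(1, 1, 1), c(2, 2, 2))),
               class = "postopsat_degenerate")
  expect_error(anova_oneway(list(c(1, 1), c(1, 1))),
               class = "postopsat_degenerate")
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(i) rnorm(sample(3:12, 1),
                                                   mean = runif(1, -1, 1)))
    got <- anova_oneway(groups)
    want <- anova_ss_oracle(groups)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df_between, k - 1)
    expect_equal(got$df_within, sum(lengths(groups)) - k)
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(12)
  for (rep in 1:10) {
    a <- rnorm(sample(4:15, 1)); b <- rnorm(sample(4:15, 1), mean = 0.5)
    f <- anova_oneway(list(a, b))$F
    t <- stats::t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t)^2, tolerance = 1e-10)
  }
})

test_that("Tukey HSD flags only genuinely separated groups", {
  g <- list(a = c(1, 2, 3, 2), b = c(1, 2, 3, 2), c = c(1, 2, 3, 2))
  tk <- tukey_hsd(g)
  expect_identical(nrow(tk), 3L)
  expect_true(all(tk$p_adj >= 0.999))
  expect_false(any(tk$reject))

  # k = 2: the adjusted p has the closed studentized-range form with k = 2,
  # which equals the two-sample equal-variance t test p
  set.seed(13)
  a <- rnorm(8); b <- rnorm(9, 1)
  tk2 <- tukey_hsd(list(a = a, b = b))
  t2 <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(tk2$p_adj, t2$p.value, tolerance = 1e-8)
  q_obs <- sqrt(2) * abs(t2$statistic)
  expect_equal(tk2$p_adj,
               1 - stats::ptukey(unname(q_obs), 2, length(a) + length(b) - 2),
               tolerance = 1e-8)

  shifted <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20) + 10)
  tk3 <- tukey_hsd(shifted)
  involves_c <- tk3$group_i == "c" | tk3$group_j == "c"
  expect_true(all(tk3$reject[involves_c]))
  expect_false(any(tk3$reject[!involves_c]))
})

test_that("contingency_test: chi-square nulls, Fisher exactness, auto selection", {
  flat <- contingency_test(matrix(c(10, 10, 10, 10), 2), "chi_square")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  diag <- contingency_test(matrix(c(5, 0, 0, 5), 2), "fisher")
  expect_equal(diag$p, 2 / 252, tolerance = 1e-12)

  expect_identical(
    contingency_test(matrix(c(2, 3, 4, 1), 2), "auto")$method, "fisher")
  expect_identical(
    contingency_test(matrix(c(20, 30, 40, 10), 2), "auto")$method,
    "chi_square")
  expect_error(contingency_test(matrix(c(0, 0, 3, 4), 2)),
               class = "postopsat_degenerate")

  set.seed(14)
  for (rep in 1:50) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(contingency_test(tab, "fisher")$p, fisher_enum_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("paired_t implements the definitional one-sample formulas", {
  r <- paired_t(c(1, 2, 3))
  expect_equal(r$mean_diff, 2)
  expect_equal(r$sd_diff, 1)
  expect_equal(r$t_stat, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_identical(r$df, 2L)

  expect_error(paired_t(rep(0, 5)), class = "postopsat_degenerate")
  expect_error(paired_t(1), class = "postopsat_argument_error")

  set.seed(15)
  for (rep in 1:20) {
    d <- rnorm(sample(3:30, 1), mean = 0.3)
    got <- paired_t(d)
    tt <- stats::t.test(d)
    expect_equal(got$t_stat, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$p_two_sided, tt$p.value, tolerance = 1e-10)
    expect_equal(c(got$ci95_low, got$ci95_high), as.numeric(tt$conf.int),
                 tolerance = 1e-10)
    # the summary-statistic route reproduces the raw-data route exactly
    sm <- paired_t_from_summary(mean(d), sd(d), length(d))
    expect_equal(sm$t_stat, got$t_stat, tolerance = 1e-10)
    expect_equal(sm$p_two_sided, got$p_two_sided, tolerance = 1e-10)
    expect_equal(sm$ci95_low, got$ci95_low, tolerance = 1e-10)
    # CI brackets the mean and t carries the sign of the mean difference
    expect_true(got$ci95_low <= got$mean_diff &&
                  got$mean_diff <= got$ci95_high)
    expect_identical(sign(got$t_stat), sign(got$mean_diff))
  }
})

test_that("published year-pair rows reproduce from their summary statistics", {
  expect_equal(round(paired_t_from_summary(0.58667, 0.38857, 6)$t_stat, 3),
               3.698)
  expect_equal(round(paired_t_from_summary(0.65167, 0.51316, 6)$t_stat, 3),
               3.111)
  expect_equal(round(paired_t_from_summary(-0.06500, 0.61452, 6)$t_stat, 3),
               -0.259)
  expect_equal(round(paired_t_from_summary(0.58667, 0.38857, 6)$p_two_sided,
                     3), 0.014)
})

test_that("Shapiro-Wilk gate rejects discrete Likert data and holds its size", {
  set.seed(16)
  lik <- sample(1:5, 500, replace = TRUE)
  expect_lt(shapiro_wilk(lik)$p, 0.05)
  expect_error(shapiro_wilk(rep(2, 10)), class = "postopsat_degenerate")
  expect_error(shapiro_wilk(c(1, 2)), class = "postopsat_argument_error")

  rejections <- vapply(1:200, function(i) {
    shapiro_wilk(rnorm(50))$p < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.05 - 0.04)
  expect_lt(mean(rejections), 0.05 + 0.04)

  # implementation cap: large samples are tested on a deterministic subsample
  expect_identical(shapiro_wilk(rnorm(6000))$n_used, 5000L)
})

test_that("spearman_rho equals Pearson on mid-ranks and is rank-invariant", {
  x <- c(3, 1, 4, 7, 5, 9, 2, 6)   # distinct values
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(sort(x), rev(sort(x)))$rho, -1)
  expect_error(spearman_rho(x, rep(1, 8)), class = "postopsat_degenerate")

  set.seed(17)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    a <- sample(1:5, n, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    got <- spearman_rho(a, b)
    expect_equal(got$rho, spearman_midrank_oracle(a, b), tolerance = 1e-12)
    # invariance under strictly monotone transforms of either argument
    expect_equal(spearman_rho(exp(a), b^3 + b)$rho, got$rho,
                 tolerance = 1e-12)
  }
})

test_that("Cronbach's alpha hits its closed-form limits", {
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  expect_equal(cronbach_alpha(matrix(c(1, 1, 2, 2, 3, 3), 3, byrow = TRUE)),
               1, tolerance = 1e-12)
  set.seed(18)
  ind <- cbind(rnorm(2000), rnorm(2000))
  expect_lt(abs(cronbach_alpha(ind)), 0.1)
  expect_error(cronbach_alpha(cbind(1:5)), class = "postopsat_argument_error")
  expect_error(cronbach_alpha(cbind(c(1, 1), c(2, 2))),
               class = "postopsat_degenerate")
})

test_that("yearly_score_summary reports moments and type-7 quartiles", {
  s <- yearly_score_summary(c(1, 2, 3), rep(2020, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$median, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$iqr_low, 1.5)
  expect_equal(s$iqr_high, 2.5)

  one <- yearly_score_summary(c(1, 2, 3, 7), c(2020, 2020, 2020, 2021))
  expect_true(is.na(one$sd[one$year == 2021]))
  expect_equal(one$mean[one$year == 2021], 7)
  expect_true(all(one$iqr_low <= one$median & one$median <= one$iqr_high))
})
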