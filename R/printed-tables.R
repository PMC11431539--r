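# The published study-design summaries (yearly counts, ward-by-year counts,
# ward age profiles, surgery percentages, Likert means, paired-test rows).
# They are the inputs that calibrate the synthetic-cohort generator and the
# reference values recomputed by verify_printed().

ward_ids <- function() {
  c("plastic_surgery", "general_surgery_1", "general_surgery_2",
    "neurosurgery", "ent", "orthopedics_1", "orthopedics_2", "urology")
}

study_years <- function() 2019:2023

#' Published study summary tables
#'
#' The printed design and result summaries of the five-year, eight-ward
#' postoperative satisfaction study, as plain R objects:
#' \describe{
#'   \item{years, wards}{the study design labels.}
#'   \item{counts}{ward x year questionnaire counts (3985 in total).}
#'   \item{ages}{ward x year mean respondent ages, plus `age_total` (the
#'     ward-level means), overall mean 53.03 and SD 15.8 years.}
#'   \item{surgery_pct}{ward x year percentage of respondents reporting
#'     surgery, plus the ward totals and the 75.13% overall rate
#'     (2994 of 3985).}
#'   \item{likert_q2, likert_q3}{ward x year mean responses to the
#'     postoperative-care and overall-impression items.}
#'   \item{education_pct}{distribution of schooling levels (percent).}
#'   \item{paired}{the ten year-pair paired-test rows: mean and SD of the
#'     differences, printed 95% CI bounds, t and p (n = 6 paired units).}
#' }
#'
#' @return A named list of data frames/matrices.
#' @export
printed_tables <- function() {
  wards <- ward_ids()
  years <- study_years()
  mk <- function(v) {
    m <- matrix(v, nrow = 8, byrow = TRUE,
                dimnames = list(wards, as.character(years)))
    m
  }
  counts <- mk(c(112, 143, 95, 68, 78,
                 126, 156, 133, 97, 162,
                 112, 129, 83, 57, 121,
                 94, 111, 81, 58, 81,
                 85, 82, 84, 57, 173,
                 88, 67, 82, 72, 151,
                 96, 73, 56, 54, 125,
                 105, 97, 117, 90, 134))
  storage.mode(counts) <- "integer"
  ages <- mk(c(43.05, 46.92, 48.33, 53.22, 46.73,
               53.48, 52.67, 52.50, 49.87, 49.13,
               56.40, 52.25, 55.53, 51.35, 54.64,
               55.20, 53.90, 53.78, 55.09, 52.91,
               49.45, 46.96, 51.71, 45.33, 47.68,
               57.52, 59.69, 54.24, 57.79, 58.66,
               56.24, 60.74, 54.57, 56.94, 56.07,
               57.02, 56.61, 56.49, 50.89, 57.44))
  age_total <- stats::setNames(
    c(47.15, 51.55, 54.19, 54.14, 48.30, 57.65, 56.89, 55.88), wards)
  surgery_pct <- mk(c(99.11, 99.30, 96.84, 88.24, 88.46,
                      63.49, 66.03, 61.65, 81.44, 82.10,
                      80.36, 75.97, 83.13, 87.72, 78.51,
                      45.74, 47.75, 54.32, 46.55, 53.09,
                      52.94, 40.24, 57.14, 50.88, 61.27,
                      90.91, 88.06, 87.80, 91.67, 90.73,
                      81.25, 90.41, 76.79, 94.44, 92.80,
                      72.38, 76.29, 76.92, 76.67, 69.40))
  surgery_total <- stats::setNames(
    c(95.56, 70.77, 80.08, 49.41, 54.26, 90.00, 87.62, 74.03), wards)
  likert_q2 <- mk(c(4.93, 4.98, 4.99, 4.88, 4.97,
                    4.23, 4.69, 4.78, 4.83, 4.80,
                    4.93, 4.78, 4.82, 4.88, 4.99,
                    4.71, 4.83, 4.64, 4.82, 4.75,
                    4.71, 4.96, 5.00, 4.78, 4.96,
                    4.70, 4.63, 4.84, 4.98, 4.79,
                    4.63, 4.42, 4.82, 4.61, 4.35,
                    4.78, 4.80, 4.76, 4.71, 4.85))
  likert_q3 <- mk(c(4.92, 4.88, 4.84, 4.88, 4.78,
                    4.11, 4.69, 4.56, 4.60, 4.74,
                    4.87, 4.73, 4.94, 4.85, 4.93,
                    4.59, 4.59, 4.39, 4.65, 4.70,
                    4.86, 4.74, 4.95, 4.70, 4.92,
                    4.60, 4.39, 4.65, 4.79, 4.78,
                    4.37, 4.15, 4.68, 4.54, 4.14,
                    4.62, 4.69, 4.65, 4.53, 4.79))
  education_pct <- c(primary = 5.20, secondary = 15.63, high_school = 52.20,
                     university = 23.41, no_answer = 3.56)
  paired <- data.frame(
    label = c("2019-2020", "2019-2021", "2019-2022", "2019-2023",
              "2020-2021", "2020-2022", "2020-2023", "2021-2022",
              "2021-2023", "2022-2023"),
    mean_diff = c(-0.06500, 0.39167, 0.30667, 0.58667, 0.45667,
                  0.37167, 0.65167, -0.08500, 0.19500, 0.28000),
    sd_diff = c(0.61452, 0.62252, 0.62073, 0.38857, 0.49156,
                0.66508, 0.51316, 0.52199, 0.26067, 0.45060),
    ci_low = c(-0.70990, -0.26163, -0.34475, 0.17889, -0.05919,
               -0.32630, 0.11313, -0.63279, -0.07856, -0.19288),
    ci_high = c(0.57990, 1.04497, 0.95808, 0.99445, 0.97252,
                1.06963, 1.19020, 0.46279, 0.46856, 0.75288),
    t = c(-0.259, 1.541, 1.210, 3.698, 2.276,
          1.369, 3.111, -0.399, 1.832, 1.522),
    p = c(0.806, 0.184, 0.280, 0.014, 0.072,
          0.229, 0.027, 0.706, 0.126, 0.188),
    stringsAsFactors = FALSE
  )
  list(years = years, wards = wards, counts = counts,
       ages = ages, age_total = age_total, age_mean = 53.03, age_sd = 15.8,
       age_range = c(12, 96),
       surgery_pct = surgery_pct, surgery_total = surgery_total,
       surgery_overall = list(operated = 2994, total = 3985, pct = 75.13),
       likert_q2 = likert_q2, likert_q3 = likert_q3,
       education_pct = education_pct,
       male_pct = 53.15, urban_pct = 44.47, rural_pct = 38.87,
       yearly_score_mean = stats::setNames(
         c(2.09, 2.16, 1.70, 1.78, 1.50), as.character(years)),
       yearly_score_sd = stats::setNames(
         c(0.52, 0.55, 0.18, 0.42, 0.14), as.character(years)),
       spearman_q2_q3 = 0.51,
       collected = 4018, retained = 3985, q2_answered = 2090,
       paired = paired)
}

#' Recompute every printed statistic that is checkable from the tables
#'
#' Executable cross-checks of the published numbers: each year-pair t, p and
#' 95% CI reconstructed from the printed (mean, SD) columns with n = 6; the
#' yearly counts summing to 3985; the ward-by-year counts summing to both
#' margins; the overall surgery percentage 2994/3985 = 75.13%; the ward
#' surgery totals and ward mean-age totals reconstructed from the year cells
#' weighted by the questionnaire counts.
#'
#' @return Data frame of class `printed_checks`: `check`, `expected`,
#'   `computed`, `tolerance`, `pass`.
#' @export
verify_printed <- function() {
  pt <- printed_tables()
  rows <- list()
  add <- function(check, expected, computed, tolerance) {
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, expected = expected, computed = computed,
      tolerance = tolerance,
      pass = is.finite(computed) && abs(computed - expected) <= tolerance,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pt$paired))) {
    r <- pt$paired[i, ]
    re <- paired_t_from_summary(r$mean_diff, r$sd_diff, 6, r$label)
    add(paste0("paired t ", r$label), r$t, round(re$t_stat, 3), 5e-4)
    add(paste0("paired p ", r$label), r$p, round(re$p_two_sided, 3), 5e-4)
    add(paste0("paired CI low ", r$label), r$ci_low, re$ci95_low, 5e-5)
    add(paste0("paired CI high ", r$label), r$ci_high, re$ci95_high, 5e-5)
  }
  add("yearly counts sum", pt$retained, sum(colSums(pt$counts)), 0)
  add("ward counts sum", pt$retained, sum(rowSums(pt$counts)), 0)
  for (y in colnames(pt$counts)) {
    add(paste0("count total ", y),
        c(`2019` = 818, `2020` = 858, `2021` = 731, `2022` = 553,
          `2023` = 1025)[[y]],
        sum(pt$counts[, y]), 0)
  }
  add("overall surgery %", pt$surgery_overall$pct,
      round(100 * pt$surgery_overall$operated / pt$surgery_overall$total, 2),
      0)
  ops <- round(pt$surgery_pct / 100 * pt$counts)
  add("implied operated count", pt$surgery_overall$operated, sum(ops), 0)
  for (w in rownames(pt$counts)) {
    add(paste0("surgery total % ", w), pt$surgery_total[[w]],
        100 * sum(ops[w, ]) / sum(pt$counts[w, ]), 0.05)
    add(paste0("mean age total ", w), pt$age_total[[w]],
        sum(pt$ages[w, ] * pt$counts[w, ]) / sum(pt$counts[w, ]), 0.1)
  }
  add("overall mean age", pt$age_mean,
      sum(pt$ages * pt$counts) / sum(pt$counts), 0.1)
  out <- do.call(rbind, rows)
  class(out) <- c("printed_checks", "data.frame")
  out
}

#' @export
print.printed_checks <- function(x, ...) {
  cat(sprintf("Printed-value checks: %d of %d pass\n", sum(x$pass), nrow(x)))
  df <- as.data.frame(x)
  df$expected <- signif(df$expected, 6)
  df$computed <- signif(df$computed, 6)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
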