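# Full trend-analysis pipeline over an exclusion-filtered survey dataset:
# design counts, age and surgery-rate tables, Likert means with ANOVA,
# algorithm scoring, yearly score summaries, all year-pair paired t tests on
# group-aggregated scores, the Shapiro-gated q2/q3 correlation, Cronbach's
# alpha and sociodemographic comparisons.

#' Pipeline settings
#'
#' @param n_groups number of paired units formed per year for the year-pair
#'   paired t tests (default 6). Scores are aggregated to group-by-year means
#'   and each year pair is compared across groups.
#' @param grouping `"specialty"` collapses ward labels that differ only by a
#'   trailing numeric suffix (e.g. two general-surgery wards) into one
#'   clinical specialty; if that does not yield `n_groups` groups, wards are
#'   assigned round-robin. `"roundrobin"` forces the latter.
#' @param policy missing-input policy for scoring, see [score_dataset()].
#' @param correct_chisq Yates continuity correction for chi-square tests.
#' @param p_adjust multiple-testing correction applied to the year-pair
#'   paired-test p values (`"none"` by default, mirroring the usual
#'   presentation; any method of [stats::p.adjust()] may be chosen).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_groups = 6,
                            grouping = c("specialty", "roundrobin"),
                            policy = c("strict", "neutral"),
                            correct_chisq = FALSE,
                            p_adjust = "none") {
  structure(list(n_groups = as.integer(n_groups),
                 grouping = match.arg(grouping),
                 policy = match.arg(policy),
                 correct_chisq = isTRUE(correct_chisq),
                 p_adjust = p_adjust),
            class = "pipeline_config")
}

# map ward labels to paired-unit groups
ward_groups <- function(wards, n_groups, grouping) {
  u <- sort(unique(wards))
  if (grouping == "specialty") {
    specialty <- sub("[ _-]*[0-9ivx]+$", "", tolower(u))
    if (length(unique(specialty)) == n_groups) {
      return(stats::setNames(specialty, u))
    }
  }
  stats::setNames(paste0("group", rep_len(seq_len(n_groups), length(u))), u)
}

try_stat <- function(expr, what, notes_env) {
  tryCatch(expr, error = function(e) {
    notes_env$skipped <- c(notes_env$skipped,
                           paste0(what, ": ", conditionMessage(e)))
    NULL
  })
}

#' Run the full trend-analysis pipeline
#'
#' Produces, from an exclusion-filtered dataset: yearly and ward-by-year
#' questionnaire counts; ward age means with an across-ward ANOVA; surgery
#' percentages with a surgery-by-year chi-square; ward-by-year Likert means
#' for both tracked items with per-ward across-year ANOVAs and a cumulative
#' (respondent-weighted) row; algorithm scoring of all operated respondents;
#' yearly score summaries; paired t tests for every unordered year pair on
#' group-aggregated scores; the Shapiro-Wilk normality gate followed by the
#' Spearman (or, if both items look normal, Pearson) correlation between the
#' two items; Cronbach's alpha; and sociodemographic comparisons of the
#' postoperative-care item by gender, residence and education. Any component
#' that cannot be computed is skipped with a recorded reason, never fatal.
#'
#' @param dataset a [survey_dataset()], already exclusion-filtered.
#' @param weights a [factor_weights()] object.
#' @param config a [pipeline_config()].
#' @return A list of class `satisfaction_report`; see the components above,
#'   plus `settings` and `skipped`.
#' @export
run_pipeline <- function(dataset, weights = factor_weights(),
                         config = pipeline_config()) {
  d <- as.data.frame(dataset)
  if (!nrow(d)) abort("empty dataset", "postopsat_data_error")
  notes <- new.env()
  notes$skipped <- character(0)

  counts_by_year <- as.data.frame(table(year = d$year),
                                  stringsAsFactors = FALSE)
  names(counts_by_year)[2] <- "n"
  counts_by_year$year <- as.integer(counts_by_year$year)

  counts_by_ward_year <- as.data.frame(table(ward = d$ward, year = d$year),
                                       stringsAsFactors = FALSE)
  names(counts_by_ward_year)[3] <- "n"
  counts_by_ward_year$year <- as.integer(counts_by_ward_year$year)

  # ages: ward x year means, ANOVA across wards
  age_rows <- stats::aggregate(age ~ ward + year, data = d, FUN = mean,
                               na.action = stats::na.omit)
  names(age_rows)[3] <- "mean_age"
  age_anova <- try_stat(
    anova_oneway(split(d$age[!is.na(d$age)], d$ward[!is.na(d$age)])),
    "age ANOVA across wards", notes)

  # surgery rates among respondents who answered q1
  q1 <- d[!is.na(d$q1_surgery), c("ward", "year", "q1_surgery")]
  surgery_rates <- NULL
  surgery_by_year <- NULL
  overall_surgery_pct <- NA_real_
  if (nrow(q1)) {
    agg <- stats::aggregate(q1_surgery == "yes" ~ ward + year, data = q1,
                            FUN = function(v) c(n = length(v), yes = sum(v)))
    m <- agg[[3]]
    surgery_rates <- data.frame(ward = agg$ward, year = agg$year,
                                n = m[, "n"],
                                pct_yes = 100 * m[, "yes"] / m[, "n"])
    overall_surgery_pct <- 100 * mean(q1$q1_surgery == "yes")
    tab <- table(q1$q1_surgery, q1$year)
    surgery_by_year <- try_stat(
      contingency_test(tab, "chi_square", correct = config$correct_chisq),
      "surgery-by-year chi-square", notes)
  } else {
    notes$skipped <- c(notes$skipped, "surgery rates: no q1 answers")
  }

  # Likert summaries + per-ward across-year ANOVA, both questions
  likert_means <- NULL
  likert_anova <- NULL
  years <- sort(unique(d$year))
  for (question in c("q2_postop_care", "q3_overall")) {
    if (all(is.na(d[[question]]))) {
      notes$skipped <- c(notes$skipped,
                         paste0(question, " analyses: no responses"))
      next
    }
    s <- likert_summary(d, question, "ward_year")
    cum <- likert_summary(d, question, "year")
    cum <- cbind(ward = "(all)", cum)
    likert_means <- rbind(likert_means, s, cum)
    for (w in c(unique(s$ward), "(all)")) {
      sub <- if (w == "(all)") d else d[d$ward == w, , drop = FALSE]
      groups <- split(sub[[question]], sub$year)
      res <- try_stat(anova_oneway(groups),
                      paste0(question, " ANOVA across years, ", w), notes)
      if (!is.null(res)) {
        likert_anova <- rbind(likert_anova, data.frame(
          ward = w, question = question, F = res$F, p = res$p,
          df_between = res$df_between, df_within = res$df_within,
          stringsAsFactors = FALSE))
      }
    }
  }

  # sociodemographic comparisons of q2
  sociodemo <- NULL
  if (!all(is.na(d$q2_postop_care))) {
    for (fac in c("gender", "residence", "education")) {
      sub <- d[!is.na(d[[fac]]) & !is.na(d$q2_postop_care), , drop = FALSE]
      groups <- split(sub$q2_postop_care, sub[[fac]])
      groups <- groups[lengths(groups) > 0]
      res <- try_stat(anova_oneway(groups),
                      paste0("q2 ANOVA by ", fac), notes)
      rows <- data.frame(
        factor = fac, level = names(groups),
        n = lengths(groups),
        mean = vapply(groups, mean, numeric(1)),
        anova_p = if (is.null(res)) NA_real_ else res$p,
        row.names = NULL, stringsAsFactors = FALSE)
      sociodemo <- rbind(sociodemo, rows)
    }
  } else {
    notes$skipped <- c(notes$skipped,
                       "sociodemographic comparisons: no q2 responses")
  }

  # algorithm scoring, yearly summaries, year-pair paired tests
  scores <- score_dataset(dataset, weights, config$policy)
  scores_by_year <- NULL
  paired_tests <- NULL
  if (nrow(scores)) {
    scores_by_year <- yearly_score_summary(scores$total, scores$year)
    if (length(years) >= 2) {
      gmap <- ward_groups(d$ward, config$n_groups, config$grouping)
      scores$group <- unname(gmap[scores$ward])
      gm <- stats::aggregate(total ~ group + year, data = scores, FUN = mean)
      pairs <- utils::combn(years, 2)
      rows <- NULL
      for (k in seq_len(ncol(pairs))) {
        y1 <- pairs[1, k]; y2 <- pairs[2, k]
        a <- gm[gm$year == y1, c("group", "total")]
        b <- gm[gm$year == y2, c("group", "total")]
        mg <- merge(a, b, by = "group", suffixes = c("_1", "_2"))
        lab <- paste0(y1, "-", y2)
        res <- try_stat(paired_t(mg$total_1 - mg$total_2, label = lab),
                        paste0("paired test ", lab), notes)
        if (!is.null(res)) rows <- rbind(rows, as_row.paired_test(res))
      }
      if (!is.null(rows) && config$p_adjust != "none") {
        rows$p_adjusted <- stats::p.adjust(rows$p_two_sided, config$p_adjust)
      }
      paired_tests <- rows
    } else {
      notes$skipped <- c(notes$skipped,
                         "paired year tests: fewer than 2 years")
    }
  } else {
    notes$skipped <- c(notes$skipped, "scoring: no scorable records")
  }

  # normality gate, then correlation between q2 and q3
  correlation <- NULL
  pair_ok <- !is.na(d$q2_postop_care) & !is.na(d$q3_overall)
  if (sum(pair_ok) >= 3) {
    x <- d$q2_postop_care[pair_ok]; y <- d$q3_overall[pair_ok]
    sw2 <- try_stat(shapiro_wilk(x), "Shapiro-Wilk q2", notes)
    sw3 <- try_stat(shapiro_wilk(y), "Shapiro-Wilk q3", notes)
    normal <- !is.null(sw2) && !is.null(sw3) &&
      sw2$p >= 0.05 && sw3$p >= 0.05
    if (normal) {
      ct <- stats::cor.test(x, y, method = "pearson")
      correlation <- list(gate = "pearson", rho = unname(ct$estimate),
                          p = ct$p.value, n = length(x),
                          shapiro_q2 = sw2, shapiro_q3 = sw3)
    } else {
      sp <- try_stat(spearman_rho(x, y), "Spearman q2 vs q3", notes)
      if (!is.null(sp)) {
        correlation <- list(gate = "spearman", rho = sp$rho, p = sp$p,
                            n = sp$n, shapiro_q2 = sw2, shapiro_q3 = sw3)
      }
    }
    alpha <- try_stat(cronbach_alpha(cbind(x, y)), "Cronbach alpha", notes)
  } else {
    notes$skipped <- c(notes$skipped,
                       "correlation: fewer than 3 complete q2/q3 pairs")
    alpha <- NULL
  }

  structure(list(
    counts_by_year = counts_by_year,
    counts_by_ward_year = counts_by_ward_year,
    ages = age_rows, age_anova = age_anova,
    surgery_rates = surgery_rates,
    overall_surgery_pct = overall_surgery_pct,
    surgery_by_year_test = surgery_by_year,
    likert_means = likert_means, likert_anova = likert_anova,
    sociodemo = sociodemo,
    scores = scores, scores_by_year = scores_by_year,
    paired_tests = paired_tests,
    correlation = correlation, cronbach = alpha,
    settings = list(config = unclass(config), weights = unclass(weights)),
    skipped = notes$skipped
  ), class = "satisfaction_report")
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat("Satisfaction trend-analysis report\n")
  cat(sprintf("  questionnaires: %d across %d year(s)\n",
              sum(x$counts_by_year$n), nrow(x$counts_by_year)))
  if (!is.na(x$overall_surgery_pct)) {
    cat(sprintf("  operated: %.2f%% of respondents\n", x$overall_surgery_pct))
  }
  if (!is.null(x$scores)) cat(sprintf("  scored records: %d\n", nrow(x$scores)))
  if (!is.null(x$scores_by_year)) {
    s <- x$scores_by_year
    cat("  yearly mean score:",
        paste(sprintf("%d=%.2f", s$year, s$mean), collapse = " "), "\n")
  }
  if (!is.null(x$paired_tests)) {
    sig <- x$paired_tests$p_two_sided < 0.05
    cat(sprintf("  paired year tests: %d (%d significant at 0.05)\n",
                nrow(x$paired_tests), sum(sig)))
  }
  if (!is.null(x$correlation)) {
    cat(sprintf("  q2~q3 correlation (%s): rho = %.2f, p = %.3g, n = %d\n",
                x$correlation$gate, x$correlation$rho, x$correlation$p,
                x$correlation$n))
  }
  if (!is.null(x$cronbach)) {
    cat(sprintf("  Cronbach alpha (q2, q3): %.2f\n", x$cronbach))
  }
  if (length(x$skipped)) {
    cat("  skipped:\n")
    for (s in x$skipped) cat("    -", s, "\n")
  }
  invisible(x)
}

#' Write a report directory
#'
#' Serialises a [run_pipeline()] report as CSV tables (`counts.csv`,
#' `ages.csv`, `surgery_rates.csv`, `likert_means.csv`, `scores.csv`,
#' `scores_by_year.csv`, `paired_tests.csv`, `correlation.csv`,
#' `sociodemographic.csv`) plus a machine-readable `summary.json` holding
#' every statistic and the settings used.
#'
#' @param report a `satisfaction_report`.
#' @param dir output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, name) {
    if (!is.null(x) && nrow(x)) {
      utils::write.csv(x, file.path(dir, name), row.names = FALSE, na = "")
    }
  }
  counts <- merge(report$counts_by_ward_year,
                  stats::setNames(report$counts_by_year, c("year", "n_year")),
                  by = "year")
  wcsv(counts, "counts.csv")
  wcsv(report$ages, "ages.csv")
  wcsv(report$surgery_rates, "surgery_rates.csv")
  if (!is.null(report$likert_means)) {
    lm <- merge(report$likert_means, report$likert_anova,
                by = c("ward", "question"), all.x = TRUE)
    wcsv(lm, "likert_means.csv")
  }
  if (!is.null(report$scores)) write_scores(report$scores, file.path(dir, "scores.csv"))
  wcsv(as.data.frame(report$scores_by_year), "scores_by_year.csv")
  wcsv(report$paired_tests, "paired_tests.csv")
  if (!is.null(report$correlation)) {
    co <- report$correlation
    wcsv(data.frame(gate = co$gate, rho = co$rho, p = co$p, n = co$n,
                    shapiro_q2_p = co$shapiro_q2$p %||% NA,
                    shapiro_q3_p = co$shapiro_q3$p %||% NA,
                    cronbach_alpha = report$cronbach %||% NA),
         "correlation.csv")
  }
  wcsv(report$sociodemo, "sociodemographic.csv")
  summary <- report
  summary$scores <- NULL # patient-level table already in scores.csv
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE, pretty = TRUE)
  invisible(dir)
}
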