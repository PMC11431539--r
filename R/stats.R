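# Statistical toolkit used by the trend pipeline: Likert summaries, one-way
# ANOVA + Tukey HSD, chi-square/Fisher, paired t (raw and from printed
# summaries), Shapiro-Wilk gate, Spearman correlation, Cronbach's alpha.
# Standard tests delegate to stats::*; the summary-statistic paired t and
# Cronbach's alpha are computed from their definitional formulas.

#' Likert summaries by ward and/or year
#'
#' Mean and SD of a 1-5 Likert item per group; missing responses are dropped
#' per cell, empty cells are omitted (and listed in the `"omitted"`
#' attribute).
#'
#' @param dataset a [survey_dataset()].
#' @param question `"q2_postop_care"` or `"q3_overall"`.
#' @param grouping `"ward_year"` (default), `"year"` or `"ward"`.
#' @return Data frame with grouping columns plus `question`, `n`, `mean`,
#'   `sd` (a single-response cell has sd 0: no observed spread).
#' @export
likert_summary <- function(dataset,
                           question = c("q2_postop_care", "q3_overall"),
                           grouping = c("ward_year", "year", "ward")) {
  question <- tryCatch(match.arg(question),
                       error = function(e) abort(
                         "unknown question id", "postopsat_argument_error"))
  grouping <- match.arg(grouping)
  d <- as.data.frame(dataset)
  keys <- switch(grouping, ward_year = c("ward", "year"),
                 year = "year", ward = "ward")
  d$.resp <- d[[question]]
  groups <- split(d$.resp, d[, keys, drop = FALSE], drop = TRUE, sep = "\r")
  rows <- lapply(names(groups), function(k) {
    v <- groups[[k]][!is.na(groups[[k]])]
    key <- strsplit(k, "\r", fixed = TRUE)[[1]]
    out <- as.list(key)
    names(out) <- keys
    out$question <- question
    out$n <- length(v)
    out$mean <- if (length(v)) mean(v) else NA_real_
    out$sd <- if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_
    out
  })
  res <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  omitted <- res[res$n == 0L, keys, drop = FALSE]
  res <- res[res$n > 0L, , drop = FALSE]
  if (!is.null(res$year)) res$year <- as.integer(res$year)
  res <- res[do.call(order, res[, keys, drop = FALSE]), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "omitted") <- omitted
  res
}

#' One-way analysis of variance
#'
#' Classical equal-variance one-way ANOVA: `F = MS_between / MS_within`.
#'
#' @param groups a list of two or more numeric vectors (each non-empty,
#'   missing values dropped).
#' @return List with `F`, `p`, `df_between`, `df_within`.
#' @export
anova_oneway <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L || any(!lengths(groups))) {
    abort("need >= 2 non-empty groups", "postopsat_argument_error")
  }
  y <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  if (length(y) <= k) {
    abort("total n must exceed the number of groups",
          "postopsat_argument_error")
  }
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ms_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2),
                          numeric(1))) / (length(y) - k)
  if (ms_within == 0) {
    if (stats::var(y) == 0) {
      abort("all values identical: F undefined", "postopsat_degenerate")
    }
    abort("zero within-group variance: F infinite", "postopsat_degenerate")
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]))
}

#' Tukey honestly-significant-difference post hoc test
#'
#' All pairwise group comparisons with familywise error controlled through
#' the studentized-range distribution, following a one-way layout.
#'
#' @inheritParams anova_oneway
#' @param conf.level confidence level of the pairwise intervals.
#' @param alpha rejection level for the `reject` flag.
#' @return Data frame with one row per unordered pair: `group_i`, `group_j`,
#'   `mean_diff`, `ci_low`, `ci_high`, `p_adj`, `reject`.
#' @export
tukey_hsd <- function(groups, conf.level = 0.95, alpha = 0.05) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) {
    abort("need >= 2 groups", "postopsat_argument_error")
  }
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  nm[nm == ""] <- paste0("g", which(nm == ""))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  data.frame(
    group_i = vapply(pairs, `[`, character(1), 2),
    group_j = vapply(pairs, `[`, character(1), 1),
    mean_diff = -tk[, "diff"],
    ci_low = -tk[, "upr"],
    ci_high = -tk[, "lwr"],
    p_adj = tk[, "p adj"],
    reject = tk[, "p adj"] < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Chi-square or Fisher exact test of a contingency table
#'
#' `method = "auto"` picks Fisher's exact test for a 2x2 table with any
#' expected cell count below 5, otherwise the Pearson chi-square (without
#' Yates continuity correction unless `correct = TRUE`).
#'
#' @param table an r x c matrix of non-negative integer counts.
#' @param method `"auto"`, `"chi_square"` or `"fisher"`.
#' @param correct apply the Yates continuity correction to the chi-square?
#' @return List with `method`, `statistic` (chi-square statistic, or the 2x2
#'   odds-ratio estimate for Fisher) and `p`.
#' @export
contingency_test <- function(table, method = c("auto", "chi_square", "fisher"),
                             correct = FALSE) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers", "postopsat_argument_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("table has a zero margin", "postopsat_degenerate")
  }
  if (method == "auto") {
    expected <- outer(rowSums(table), colSums(table)) / sum(table)
    method <- if (all(dim(table) == 2L) && any(expected < 5)) {
      "fisher"
    } else {
      "chi_square"
    }
  }
  if (method == "fisher") {
    ft <- stats::fisher.test(table)
    list(method = "fisher",
         statistic = if (all(dim(table) == 2L)) unname(ft$estimate) else NA,
         p = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
    list(method = "chi_square", statistic = unname(ct$statistic),
         p = ct$p.value)
  }
}

# shared core for the two paired-t entry points
paired_t_core <- function(mean_diff, sd_diff, n, label) {
  se <- sd_diff / sqrt(n)
  t <- mean_diff / se
  df <- n - 1L
  p <- 2 * stats::pt(-abs(t), df)
  half <- stats::qt(0.975, df) * se
  structure(list(label = label, mean_diff = mean_diff, sd_diff = sd_diff,
                 n_pairs = n, t_stat = t, df = df, p_two_sided = p,
                 ci95_low = mean_diff - half, ci95_high = mean_diff + half),
            class = "paired_test")
}

#' Paired-samples t test from raw differences
#'
#' One-sample t test of the within-pair differences: `t = mean / (sd/sqrt(n))`
#' with `n - 1` degrees of freedom, two-sided p, and the 95% confidence
#' interval `mean +/- t_{0.975, n-1} * sd/sqrt(n)`.
#'
#' @param differences numeric vector of paired differences (n >= 2, missing
#'   values dropped; their SD must be positive).
#' @param label optional label for the pair (e.g. `"2019-2023"`).
#' @return A `paired_test` object: `label`, `mean_diff`, `sd_diff`, `n_pairs`,
#'   `t_stat`, `df`, `p_two_sided`, `ci95_low`, `ci95_high`.
#' @export
paired_t <- function(differences, label = NA_character_) {
  d <- differences[!is.na(differences)]
  if (length(d) < 2L) {
    abort("need >= 2 paired differences", "postopsat_argument_error")
  }
  s <- stats::sd(d)
  if (s == 0) {
    abort("zero variance of differences: t undefined", "postopsat_degenerate")
  }
  paired_t_core(mean(d), s, length(d), label)
}

#' Paired-samples t test from printed summary statistics
#'
#' Identical formulas to [paired_t()], but starting from the mean and SD of
#' the differences; this is how a printed paired-samples table row (mean, SD,
#' n) is verified without the raw data.
#'
#' @param mean_diff mean of the paired differences.
#' @param sd_diff standard deviation of the differences (> 0).
#' @param n_pairs number of pairs (>= 2).
#' @inheritParams paired_t
#' @return A `paired_test` object.
#' @examples
#' paired_t_from_summary(0.58667, 0.38857, 6)$t_stat # 3.698
#' @export
paired_t_from_summary <- function(mean_diff, sd_diff, n_pairs,
                                  label = NA_character_) {
  if (!is.numeric(n_pairs) || n_pairs < 2L) {
    abort("n_pairs must be >= 2", "postopsat_argument_error")
  }
  if (!is.numeric(sd_diff) || sd_diff <= 0) {
    abort("sd_diff must be > 0", "postopsat_degenerate")
  }
  paired_t_core(mean_diff, sd_diff, as.integer(n_pairs), label)
}

#' @export
print.paired_test <- function(x, ...) {
  lab <- if (is.na(x$label)) "" else paste0(" [", x$label, "]")
  cat(sprintf(
    "Paired t%s: mean %.5f, sd %.5f, n %d -> t = %.3f, df = %d, p = %.3f\n",
    lab, x$mean_diff, x$sd_diff, x$n_pairs, x$t_stat, x$df, x$p_two_sided))
  cat(sprintf("  95%% CI [%.5f, %.5f]\n", x$ci95_low, x$ci95_high))
  invisible(x)
}

as_row.paired_test <- function(x) {
  data.frame(label = x$label, mean_diff = x$mean_diff, sd_diff = x$sd_diff,
             n_pairs = x$n_pairs, ci95_low = x$ci95_low,
             ci95_high = x$ci95_high, t_stat = x$t_stat, df = x$df,
             p_two_sided = x$p_two_sided, stringsAsFactors = FALSE)
}

#' Shapiro-Wilk normality test
#'
#' Used as the gate that selects the rank-based Spearman correlation over the
#' moment-based Pearson correlation: a small p means the responses are not
#' plausibly normal. For n above 5000 a deterministic evenly spaced
#' subsample of 5000 values is tested (the test's implementation limit).
#'
#' @param values numeric vector, n >= 3 after dropping missing values.
#' @return List with `W`, `p` and `n_used`.
#' @export
shapiro_wilk <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 3L) abort("need n >= 3", "postopsat_argument_error")
  if (stats::var(v) == 0) {
    abort("constant input: W undefined", "postopsat_degenerate")
  }
  if (length(v) > 5000L) {
    v <- v[round(seq(1L, length(v), length.out = 5000L))]
  }
  st <- stats::shapiro.test(v)
  list(W = unname(st$statistic), p = st$p.value, n_used = length(v))
}

#' Spearman rank correlation
#'
#' The Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p value from the large-sample t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length; pairs with a missing value are
#'   dropped; at least 3 complete pairs are required.
#' @return List with `rho`, `p`, `n` and `method`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", "postopsat_argument_error")
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need >= 3 complete pairs", "postopsat_argument_error")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("constant input: rank variance is zero", "postopsat_degenerate")
  }
  rho <- stats::cor(x, y, method = "spearman")
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p = p, n = n, method = "t-approximation")
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(row sums))`, with the
#' unbiased variance estimator and row-wise deletion of incomplete rows.
#'
#' @param items an n x k numeric matrix or data frame (k >= 2 items).
#' @return The alpha coefficient.
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (ncol(m) < 2L) abort("need k >= 2 items", "postopsat_argument_error")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2L) {
    abort("need >= 2 complete rows", "postopsat_argument_error")
  }
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    abort("zero variance of the total score: alpha undefined",
          "postopsat_degenerate")
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Yearly summaries of algorithm totals
#'
#' Mean, unbiased SD, median and the 25th/75th percentiles (linear
#' interpolation, quantile type 7) of the total score per year — the numbers
#' behind a box-plot presentation of the score's evolution.
#'
#' @param scores numeric vector of algorithm totals.
#' @param years parallel vector of calendar years.
#' @return Data frame of class `yearly_scores`: `year`, `n`, `mean`, `sd`,
#'   `median`, `iqr_low`, `iqr_high` (SD is `NA` when a year has one score).
#' @export
yearly_score_summary <- function(scores, years) {
  if (length(scores) != length(years)) {
    abort("scores and years must have equal length",
          "postopsat_argument_error")
  }
  ok <- !is.na(scores) & !is.na(years)
  scores <- scores[ok]; years <- years[ok]
  if (!length(scores)) abort("no scores", "postopsat_argument_error")
  rows <- lapply(split(scores, years), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               median = q[2], iqr_low = q[1], iqr_high = q[3])
  })
  out <- do.call(rbind, rows)
  out <- cbind(year = as.integer(names(rows)), out)
  rownames(out) <- NULL
  class(out) <- c("yearly_scores", "data.frame")
  out
}

#' @export
print.yearly_scores <- function(x, ...) {
  cat("Yearly algorithm-score summaries\n")
  print.data.frame(within(as.data.frame(x), {
    mean <- round(mean, 2); sd <- round(sd, 2); median <- round(median, 2)
    iqr_low <- round(iqr_low, 2); iqr_high <- round(iqr_high, 2)
  }))
  invisible(x)
}
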