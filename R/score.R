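#' Age factor of the satisfaction algorithm
#'
#' `age_base + age_slope * (age / 10)`: the factor grows by `age_slope`
#' (default 0.1) per decade of life, reflecting slower recovery at older ages.
#' Age is used as a continuous value; fractional ages are allowed.
#'
#' @param age age in years, non-negative. Vectorised.
#' @param weights a [factor_weights()] object.
#' @return Numeric factor value(s).
#' @examples
#' age_factor(50) # 1.5
#' @export
age_factor <- function(age, weights = factor_weights()) {
  if (length(age) == 0L || anyNA(age) || !is.numeric(age)) {
    abort("age must be numeric and non-missing", "postopsat_missing_input")
  }
  if (any(age < 0)) abort("age must be >= 0", "postopsat_domain_error")
  weights$age_base + weights$age_slope * (age / 10)
}

#' Pain factor of the satisfaction algorithm
#'
#' `pain_base + pain_slope * pain` on the 0-10 numeric pain rating scale
#' (default: 1.0 at no pain up to 2.0 at worst pain).
#'
#' @param pain pain rating in `[0, 10]`. Vectorised.
#' @inheritParams age_factor
#' @return Numeric factor value(s).
#' @examples
#' pain_factor(3) # 1.3
#' @export
pain_factor <- function(pain, weights = factor_weights()) {
  if (length(pain) == 0L || anyNA(pain) || !is.numeric(pain)) {
    abort("pain must be numeric and non-missing", "postopsat_missing_input")
  }
  if (any(pain < 0 | pain > 10)) {
    abort("pain must be in [0, 10]", "postopsat_domain_error")
  }
  weights$pain_base + weights$pain_slope * pain
}

#' Categorical factor of the satisfaction algorithm
#'
#' Looks up the configured constant for one level of a categorical input.
#' Levels: gender male/female; residence urban/rural; infection, complication,
#' innovation yes/no; protocol standard/personalized.
#'
#' @param field one of `"gender"`, `"residence"`, `"infection"`,
#'   `"complication"`, `"protocol"`, `"innovation"`.
#' @param value the level; `NA` raises a missing-input error (the scoring
#'   policy in [score_dataset()] decides upstream what to do about missing
#'   inputs).
#' @inheritParams age_factor
#' @return The factor value.
#' @examples
#' categorical_factor("complication", "yes") # 2.0
#' @export
categorical_factor <- function(field, value, weights = factor_weights()) {
  field <- match.arg(field, c("gender", "residence", "infection",
                              "complication", "protocol", "innovation"))
  if (length(value) != 1L || is.na(value)) {
    abort(paste0("missing input: ", field), "postopsat_missing_input")
  }
  map <- switch(field,
    gender = c(male = weights$gender_male, female = weights$gender_female),
    residence = c(urban = weights$env_urban, rural = weights$env_rural),
    infection = c(yes = weights$infection_yes, no = weights$infection_no),
    complication = c(yes = weights$complication_yes,
                     no = weights$complication_no),
    protocol = c(standard = weights$protocol_standard,
                 personalized = weights$protocol_personalized),
    innovation = c(yes = weights$innovation_used, no = weights$innovation_none)
  )
  if (!value %in% names(map)) {
    abort(paste0("'", value, "' is not a level of ", field,
                 " (levels: ", paste(names(map), collapse = ", "), ")"),
          "postopsat_domain_error")
  }
  unname(map[[value]])
}

#' Interpretation band of a total score
#'
#' Higher totals mean lower satisfaction: `"high"` satisfaction for totals
#' up to `high_threshold` (<= 1.5 by default), `"moderate"` above that and up
#' to `low_threshold` (<= 3.0), `"low"` strictly above `low_threshold`.
#' Both boundaries are inclusive on the more-satisfied side, so a total of
#' exactly 1.5 is "high" and exactly 3.0 is "moderate".
#'
#' @param total positive total score(s).
#' @inheritParams age_factor
#' @return Character vector in `c("high", "moderate", "low")`.
#' @examples
#' categorize(c(1.5, 3.0, 3.0000001)) # high moderate low
#' @export
categorize <- function(total, weights = factor_weights()) {
  if (length(total) == 0L || anyNA(total) || !is.numeric(total)) {
    abort("total must be numeric and non-missing", "postopsat_domain_error")
  }
  if (any(total <= 0)) abort("total must be > 0", "postopsat_domain_error")
  ifelse(total <= weights$high_threshold, "high",
         ifelse(total <= weights$low_threshold, "moderate", "low"))
}

# the eight factor values for vectors of inputs; NA inputs give NA factors
# (policy resolution happens in the callers).
score_factors <- function(gender, age, residence, infection, complication,
                          protocol, innovation, pain, weights) {
  lv <- function(x, yes, no, a, b) {
    out <- rep(NA_real_, length(x))
    out[!is.na(x) & x == a] <- yes
    out[!is.na(x) & x == b] <- no
    out
  }
  data.frame(
    gender = lv(gender, weights$gender_male, weights$gender_female,
                "male", "female"),
    age = ifelse(is.na(age), NA_real_,
                 weights$age_base + weights$age_slope * (age / 10)),
    environment = lv(residence, weights$env_urban, weights$env_rural,
                     "urban", "rural"),
    infection = lv(infection, weights$infection_yes, weights$infection_no,
                   "yes", "no"),
    complication = lv(complication, weights$complication_yes,
                      weights$complication_no, "yes", "no"),
    protocol = lv(protocol, weights$protocol_standard,
                  weights$protocol_personalized, "standard", "personalized"),
    innovation = lv(innovation, weights$innovation_used,
                    weights$innovation_none, "yes", "no"),
    pain = ifelse(is.na(pain), NA_real_,
                  weights$pain_base + weights$pain_slope * pain)
  )
}

#' Total satisfaction score of one respondent
#'
#' Multiplies the eight factor values (gender, age, environment, infection,
#' complication, protocol, innovation, pain) and assigns the interpretation
#' band. The record must report having undergone surgery.
#'
#' @param record a single questionnaire record: a list or one-row data frame
#'   with fields `q1_surgery`, `gender`, `age`, `residence`, `infection`,
#'   `complication`, `protocol`, `innovation`, `pain`.
#' @inheritParams age_factor
#' @param policy `"strict"` (default) errors on any missing input, listing the
#'   fields; `"neutral"` substitutes the neutral factor value 1.0 for missing
#'   categorical/pain/age inputs.
#' @return A `satisfaction_score`: list with `total`, `category` and
#'   `factors` (the eight factor values used).
#' @examples
#' r <- list(q1_surgery = "yes", gender = "male", age = 50,
#'           residence = "urban", infection = "yes", complication = "no",
#'           protocol = "standard", innovation = "no", pain = 5)
#' total_score(r)$total # 5.265
#' @export
total_score <- function(record, weights = factor_weights(),
                        policy = c("strict", "neutral")) {
  policy <- match.arg(policy)
  record <- as.list(record)
  if (is.null(record$q1_surgery) || is.na(record$q1_surgery) ||
      record$q1_surgery != "yes") {
    abort("record does not report surgery (q1_surgery != 'yes')",
          "postopsat_domain_error")
  }
  g <- function(f) if (is.null(record[[f]])) NA else record[[f]]
  if (!is.na(g("age")) && g("age") < 0) {
    abort("age must be >= 0", "postopsat_domain_error")
  }
  if (!is.na(g("pain")) && (g("pain") < 0 || g("pain") > 10)) {
    abort("pain must be in [0, 10]", "postopsat_domain_error")
  }
  f <- score_factors(g("gender"), g("age"), g("residence"), g("infection"),
                     g("complication"), g("protocol"), g("innovation"),
                     g("pain"), weights)
  f <- unlist(f[1, ])
  if (anyNA(f)) {
    if (policy == "strict") {
      abort(paste0("missing input(s): ",
                   paste(names(f)[is.na(f)], collapse = ", ")),
            "postopsat_missing_input")
    }
    f[is.na(f)] <- 1.0
  }
  total <- prod(f)
  structure(list(total = total,
                 category = categorize(total, weights),
                 factors = f),
            class = "satisfaction_score")
}

#' @export
print.satisfaction_score <- function(x, ...) {
  cat(sprintf("Satisfaction score: %.4f (%s satisfaction)\n",
              x$total, x$category))
  cat("  factors:",
      paste(sprintf("%s=%.3g", names(x$factors), x$factors), collapse = " "),
      "\n")
  invisible(x)
}

#' Score every operated respondent in a dataset
#'
#' Applies the satisfaction algorithm to each record with `q1_surgery = "yes"`
#' and resolvable inputs. Non-operated records, records with a missing surgery
#' answer and (under the strict policy) records with missing algorithm inputs
#' are skipped, never fatal; the skip tally by reason is attached as the
#' `"skipped"` attribute.
#'
#' @param dataset a [survey_dataset()].
#' @inheritParams total_score
#' @return A data frame of class `score_table` with columns `record_id`,
#'   `year`, `ward`, `total` and `category`, plus attribute `skipped`
#'   (data frame of reason/n).
#' @export
score_dataset <- function(dataset, weights = factor_weights(),
                          policy = c("strict", "neutral")) {
  policy <- match.arg(policy)
  d <- as.data.frame(dataset)
  n <- nrow(d)
  id <- seq_len(n)
  skipped <- character(0)

  operated <- !is.na(d$q1_surgery) & d$q1_surgery == "yes"
  if (any(!operated)) {
    skipped <- c(skipped, ifelse(is.na(d$q1_surgery[!operated]),
                                 "surgery answer missing", "not operated"))
  }
  ds <- d[operated, , drop = FALSE]
  f <- score_factors(ds$gender, ds$age, ds$residence, ds$infection,
                     ds$complication, ds$protocol, ds$innovation, ds$pain,
                     weights)
  if (policy == "strict") {
    miss <- is.na(as.matrix(f))
    ok <- !apply(miss, 1, any)
    if (any(!ok)) {
      reason <- apply(miss[!ok, , drop = FALSE], 1, function(m) {
        paste0("missing: ", paste(colnames(miss)[m], collapse = ", "))
      })
      skipped <- c(skipped, reason)
    }
  } else {
    f[is.na(f)] <- 1.0
    ok <- rep(TRUE, nrow(ds))
  }
  fs <- f[ok, , drop = FALSE]
  total <- Reduce(`*`, fs)
  if (length(total) == 0L) total <- numeric(0)
  out <- data.frame(
    record_id = id[operated][ok],
    year = ds$year[ok],
    ward = ds$ward[ok],
    total = total,
    category = if (length(total)) categorize(total, weights) else character(0),
    stringsAsFactors = FALSE
  )
  tab <- table(skipped)
  attr(out, "skipped") <- data.frame(reason = names(tab),
                                     n = as.integer(tab),
                                     stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("Scored %d record(s)\n", nrow(x)))
  sk <- attr(x, "skipped")
  if (!is.null(sk) && nrow(sk)) {
    cat("Skipped:\n")
    for (i in seq_len(nrow(sk))) {
      cat(sprintf("  %-40s %d\n", sk$reason[i], sk$n[i]))
    }
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Box-plot of total scores by year
#'
#' Yearly distribution of algorithm totals: the box is the interquartile
#' range, the heavy line the median (the usual presentation for this score).
#'
#' @param x a `score_table` from [score_dataset()].
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.score_table <- function(x, ...) {
  graphics::boxplot(total ~ year, data = x,
                    xlab = "year", ylab = "algorithm total score", ...)
  invisible(x)
}

#' Write a scored table to CSV
#'
#' Columns `record_id, year, ward, total_score, category`; totals are written
#' with six decimal places.
#'
#' @param scores a `score_table`.
#' @param path output file path.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(record_id = scores$record_id, year = scores$year,
                    ward = scores$ward,
                    total_score = sprintf("%.6f", scores$total),
                    category = scores$category)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
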