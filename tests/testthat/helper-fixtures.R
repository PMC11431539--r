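# Shared fixtures and independent oracles. The default synthetic cohort takes
# a couple of seconds to calibrate and draw, so it is generated once per test
# run and cached.

.fixtures <- new.env()

default_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$config <- default_config()
    .fixtures$cohort <- suppressWarnings(generate_cohort(.fixtures$config))
  }
  .fixtures$cohort
}

default_cohort_config <- function() {
  default_cohort()
  .fixtures$config
}

retained_cohort <- function() {
  if (is.null(.fixtures$retained)) {
    .fixtures$retained <- apply_exclusion(default_cohort())$retained
  }
  .fixtures$retained
}

# one complete, operated questionnaire record; override fields via ...
make_record <- function(...) {
  utils::modifyList(list(
    year = 2020, ward = "urology", age = 50, gender = "female",
    residence = "rural", education = "secondary", q1_surgery = "yes",
    q2_postop_care = 4L, q3_overall = 4L, infection = "no",
    complication = "no", protocol = "standard", innovation = "no", pain = 0L
  ), list(...))
}

records_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) as.data.frame(r,
                                                        stringsAsFactors = FALSE)))
}

# n random complete operated records (uniform over factor levels)
random_records <- function(n) {
  data.frame(
    year = sample(2019:2023, n, replace = TRUE),
    ward = sample(letters[1:8], n, replace = TRUE),
    age = round(stats::runif(n, 0, 96), 1),
    gender = sample(c("male", "female"), n, replace = TRUE),
    residence = sample(c("urban", "rural"), n, replace = TRUE),
    education = sample(c("primary", "secondary", "high_school", "university"),
                       n, replace = TRUE),
    q1_surgery = "yes",
    q2_postop_care = sample(1:5, n, replace = TRUE),
    q3_overall = sample(1:5, n, replace = TRUE),
    infection = sample(c("yes", "no"), n, replace = TRUE),
    complication = sample(c("yes", "no"), n, replace = TRUE),
    protocol = sample(c("standard", "personalized"), n, replace = TRUE),
    innovation = sample(c("yes", "no"), n, replace = TRUE),
    pain = sample(0:10, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# --- independent oracles ------------------------------------------------------

# one-way ANOVA from the definitional sums of squares
anova_ss_oracle <- function(groups) {
  y <- unlist(groups)
  k <- length(groups)
  n <- length(y)
  gm <- mean(y)
  ss_between <- sum(vapply(groups, function(g) {
    length(g) * (mean(g) - gm)^2
  }, numeric(1)))
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                          numeric(1)))
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# two-sided Fisher exact p for a 2x2 table by exhaustive enumeration of all
# hypergeometric tables with the observed margins (point probabilities from
# log-binomial coefficients; the customary 1e-7 relative tie tolerance)
fisher_enum_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mid-ranks computed by explicit sorting (no call to rank())
midranks <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Spearman as the definitional Pearson formula applied to mid-ranks
spearman_midrank_oracle <- function(x, y) {
  a <- midranks(x); b <- midranks(y)
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
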