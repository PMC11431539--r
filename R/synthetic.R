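# Synthetic questionnaire-cohort generator. Emulates the published 8-ward x
# 5-year design: ward-by-year questionnaire counts, surgery rates, ward age
# profiles (truncated normal), demographic margins, ward-by-year Likert means
# reached by thresholding a correlated latent pair, clinical rates calibrated
# so the yearly mean algorithm score matches the published trajectory, field
# missingness, and a block of grossly incomplete records that the >20%
# missingness rule must catch.

#' Synthetic cohort configuration calibrated to the published study
#'
#' Returns the full generative description of a synthetic cohort whose
#' defaults are the published marginal summaries: ward-by-year counts
#' (3985 questionnaires), surgery probabilities, ward age means (SD 15.8,
#' truncated to 12-96 years), gender/residence/education margins,
#' ward-by-year Likert target means for both items, a rank-correlation target
#' of 0.51 between the two items, and per-year clinical rates calibrated in
#' closed form so the expected yearly mean algorithm score equals the
#' published trajectory (2.09, 2.16, 1.70, 1.78, 1.50). On top of the 3985
#' well-formed records, 33 grossly incomplete records are generated
#' (4018 collected in total), mirroring the published quality-control counts.
#'
#' Infection, complication, protocol-adoption, innovation and pain rates are
#' not reported in the study; the defaults here are calibrated to the score
#' trajectory, not observed values. The infection/complication/pain
#' trajectories are fixed (slight 2020 worsening, improvement afterwards) and
#' the per-year personalized-protocol/innovation adoption probability is
#' solved from the score target.
#'
#' @param seed integer seed; every random draw of [generate_cohort()] flows
#'   from it.
#' @param weights the [factor_weights()] the clinical calibration assumes.
#' @return A list of class `synthetic_config`.
#' @export
default_config <- function(seed = 20240912, weights = factor_weights()) {
  pt <- printed_tables()
  cfg <- list(
    seed = as.integer(seed),
    years = pt$years,
    wards = pt$wards,
    cell_counts = pt$counts,
    surgery_prob = pt$surgery_pct / 100,
    age_mean = pt$age_total,
    age_sd = pt$age_sd,
    age_range = pt$age_range,
    male_prob = pt$male_pct / 100,
    residence_probs = c(urban = pt$urban_pct / 100,
                        rural = pt$rural_pct / 100,
                        missing = 1 - (pt$urban_pct + pt$rural_pct) / 100),
    education_probs = c(primary = 0.0520, secondary = 0.1563,
                        high_school = 0.5220, university = 0.2341,
                        missing = 0.0356),
    likert_q2 = pt$likert_q2,
    likert_q3 = pt$likert_q3,
    latent_corr = pt$spearman_q2_q3,
    score_targets = pt$yearly_score_mean,
    clinical = list(
      infection = c(0.05, 0.06, 0.02, 0.03, 0.01),
      complication = c(0.06, 0.07, 0.02, 0.03, 0.01),
      pain_mean = c(1.0, 1.1, 0.5, 0.6, 0.2)
    ),
    missing_rate = list(age = 0.02, gender = 0.01,
                        q2_postop_care = 1 - pt$q2_answered / 2994,
                        q3_overall = 0.05,
                        infection = 0.02, complication = 0.02,
                        protocol = 0.02, innovation = 0.02, pain = 0.02),
    gross_missing = as.integer(pt$collected - pt$retained),
    exclusion_threshold = 0.20
  )
  for (f in c("infection", "complication", "pain_mean")) {
    names(cfg$clinical[[f]]) <- as.character(cfg$years)
  }
  cfg$clinical$adoption <- calibrate_adoption(cfg, weights)
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort config: %d wards x %d years, %d records (+%d gross-missing), seed %d\n",
    length(x$wards), length(x$years), sum(x$cell_counts), x$gross_missing,
    x$seed))
  cat("  yearly score targets:",
      paste(sprintf("%s=%.2f", names(x$score_targets), x$score_targets),
            collapse = " "), "\n")
  cat("  calibrated adoption:",
      paste(sprintf("%s=%.2f", names(x$clinical$adoption),
                    x$clinical$adoption), collapse = " "), "\n")
  invisible(x)
}

#' Read a synthetic-cohort configuration from JSON
#'
#' Scalar fields and the per-year clinical/missingness rates may be
#' overridden; anything absent keeps its [default_config()] value. Matrices
#' (`cell_counts`, `surgery_prob`, `likert_q2`, `likert_q3`) are given as
#' ward-by-year row-major lists.
#'
#' @param path JSON file path.
#' @param seed optional seed override.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), "postopsat_config_error")
  }
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(
                    paste0("malformed JSON config: ", conditionMessage(e)),
                    "postopsat_config_error"))
  cfg <- default_config(seed = raw$seed %||% 20240912)
  scalar <- intersect(names(raw),
                      c("seed", "male_prob", "age_sd", "latent_corr",
                        "gross_missing", "exclusion_threshold"))
  for (f in scalar) cfg[[f]] <- raw[[f]]
  for (f in intersect(names(raw), c("residence_probs", "education_probs",
                                    "score_targets", "age_mean"))) {
    v <- unlist(raw[[f]])
    cfg[[f]][names(v)] <- v
  }
  for (f in intersect(names(raw$missing_rate) %||% character(0),
                      names(cfg$missing_rate))) {
    cfg$missing_rate[[f]] <- raw$missing_rate[[f]]
  }
  mats <- intersect(names(raw),
                    c("cell_counts", "surgery_prob", "likert_q2", "likert_q3"))
  for (f in mats) {
    m <- matrix(unlist(raw[[f]]), nrow = length(cfg$wards), byrow = TRUE,
                dimnames = dimnames(cfg$cell_counts))
    cfg[[f]] <- m
  }
  if (!is.null(seed)) cfg$seed <- seed
  cfg$seed <- as.integer(cfg$seed)
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  if (any(cfg$cell_counts < 0) ||
      any(cfg$cell_counts != round(cfg$cell_counts))) {
    abort("cell_counts must be non-negative integers",
          "postopsat_config_error")
  }
  probs <- c(cfg$surgery_prob, cfg$male_prob, cfg$residence_probs,
             cfg$education_probs, unlist(cfg$missing_rate))
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]", "postopsat_config_error")
  }
  lik <- c(cfg$likert_q2, cfg$likert_q3)
  if (any(lik < 1 | lik > 5)) {
    abort("likert target means must lie in [1, 5]", "postopsat_config_error")
  }
  structure(cfg, class = "synthetic_config")
}

# Likert cutpoint calibration --------------------------------------------------

#' Calibrate latent cutpoints for a target Likert mean
#'
#' Finds four ordered cutpoints on a zero-mean normal latent variable such
#' that thresholding it into the five categories yields the target mean: a
#' symmetric base cutpoint set is shifted by a scalar solved with
#' [stats::uniroot()]. The implied mean is exact to the root tolerance
#' (far inside the 0.01 contract).
#'
#' @param target_mean desired category mean, strictly inside (1, 5).
#' @param latent_sd standard deviation of the latent normal.
#' @param base base cutpoints (defaults to -1.5, -0.5, 0.5, 1.5, which give
#'   mean 3 unshifted).
#' @return Numeric vector of 4 increasing cutpoints, with the achieved mean
#'   as attribute `implied_mean`.
#' @export
calibrate_cutpoints <- function(target_mean, latent_sd = 1,
                                base = c(-1.5, -0.5, 0.5, 1.5)) {
  if (!is.numeric(target_mean) || length(target_mean) != 1L ||
      target_mean <= 1 || target_mean >= 5) {
    abort("target_mean must lie strictly inside (1, 5)",
          "postopsat_calibration_error")
  }
  f <- function(s) 1 + sum(stats::pnorm(s - base)) - target_mean
  sol <- tryCatch(
    stats::uniroot(f, c(-15, 15), tol = 1e-10),
    error = function(e) abort(
      paste0("cutpoint calibration failed: ", conditionMessage(e)),
      "postopsat_calibration_error"))
  cuts <- (base - sol$root) * latent_sd
  attr(cuts, "implied_mean") <- 1 + sum(stats::pnorm(sol$root - base))
  cuts
}

# category probabilities implied by cutpoints (standard-normal latent)
implied_likert_probs <- function(cuts, latent_sd = 1) {
  p <- stats::pnorm(c(cuts / latent_sd, Inf))
  diff(c(0, p))
}

implied_likert_mean <- function(cuts, latent_sd = 1) {
  sum(seq_len(5) * implied_likert_probs(cuts, latent_sd))
}

# Bivariate-normal rectangle probabilities -------------------------------------

# 5x5 joint category probabilities when a standard bivariate normal pair with
# correlation rho is thresholded at cut_x / cut_y. Computed by cumulative
# trapezoid integration of phi(x) * Phi((k - rho x)/sqrt(1-rho^2)); the grid
# is fine enough for ~1e-8 accuracy, which the calibration root-find needs.
bvn_cell_probs <- function(cut_x, cut_y, rho) {
  if (abs(rho) >= 1) abort("|rho| must be < 1", "postopsat_domain_error")
  grid <- seq(-9, 9, length.out = 2049)
  s <- sqrt(1 - rho^2)
  phi <- stats::dnorm(grid)
  # F[i, j] = P(X <= cut_x[i], Y <= cut_y[j]) on the 4 x 4 interior grid
  Fmat <- matrix(0, 6, 6)
  for (j in 1:4) {
    g <- phi * stats::pnorm((cut_y[j] - rho * grid) / s)
    cum <- c(0, cumsum((g[-1] + g[-length(g)]) / 2)) * diff(grid)[1]
    Fmat[2:5, j + 1] <- stats::approx(grid, cum, xout = cut_x, rule = 2)$y
  }
  Fmat[6, 2:5] <- stats::pnorm(cut_y)   # X <= Inf
  Fmat[2:5, 6] <- stats::pnorm(cut_x)   # Y <= Inf
  Fmat[6, 6] <- 1
  P <- Fmat[-1, -1] - Fmat[-6, -1] - Fmat[-1, -6] + Fmat[-6, -6]
  pmax(P, 0)
}

# population Spearman (grade) correlation of a discrete 5x5 joint table,
# i.e. what the sample mid-rank Spearman estimates under ties.
population_spearman <- function(P) {
  p <- rowSums(P); q <- colSums(P)
  a <- cumsum(p) - p / 2
  b <- cumsum(q) - q / 2
  mu_a <- sum(p * a); mu_b <- sum(q * b)
  va <- sum(p * a^2) - mu_a^2
  vb <- sum(q * b^2) - mu_b^2
  if (va <= 0 || vb <= 0) {
    abort("degenerate margin: grade variance zero", "postopsat_degenerate")
  }
  (sum(P * outer(a, b)) - mu_a * mu_b) / sqrt(va * vb)
}

# cutpoints for every ward x year cell and both questions, with infeasible
# targets (at or beyond the scale ends) clamped and collected
calibrate_cells <- function(cfg) {
  clamp <- function(m) pmin(pmax(m, 1.01), 4.99)
  clamped <- c(
    if (any(cfg$likert_q2 != clamp(cfg$likert_q2)))
      paste0("q2:", paste(which(cfg$likert_q2 != clamp(cfg$likert_q2)),
                          collapse = ",")),
    if (any(cfg$likert_q3 != clamp(cfg$likert_q3)))
      paste0("q3:", paste(which(cfg$likert_q3 != clamp(cfg$likert_q3)),
                          collapse = ",")))
  cuts <- function(m) apply(clamp(m), c(1, 2), function(t) {
    list(calibrate_cutpoints(t))
  })
  list(q2 = cuts(cfg$likert_q2), q3 = cuts(cfg$likert_q3),
       implied_q2 = apply(clamp(cfg$likert_q2), c(1, 2),
                          function(t) implied_likert_mean(
                            calibrate_cutpoints(t))),
       implied_q3 = apply(clamp(cfg$likert_q3), c(1, 2),
                          function(t) implied_likert_mean(
                            calibrate_cutpoints(t))),
       clamped = clamped)
}

# latent correlation that makes the pooled mid-rank Spearman of the
# discretised (q2, q3) pair hit the target, accounting for the ward x year
# mixture (weights: expected operated counts) and the per-cell cutpoints
calibrate_latent_corr <- function(cfg, cells = calibrate_cells(cfg)) {
  w <- cfg$cell_counts * cfg$surgery_prob
  keep <- which(w > 0)
  if (!length(keep)) return(list(rho = 0, achieved = NA_real_))
  w <- w[keep] / sum(w[keep])
  pooled <- function(rho) {
    P <- matrix(0, 5, 5)
    for (i in seq_along(keep)) {
      k <- keep[i]
      P <- P + w[i] * bvn_cell_probs(cells$q2[[k]][[1]],
                                     cells$q3[[k]][[1]], rho)
    }
    population_spearman(P / sum(P))
  }
  f <- function(rho) pooled(rho) - cfg$latent_corr
  hi <- 0.995
  if (f(hi) < 0) {
    warn(sprintf(
      "rank-correlation target %.2f unreachable; latent correlation clamped",
      cfg$latent_corr), "postopsat_calibration_warning")
    return(list(rho = hi, achieved = pooled(hi)))
  }
  sol <- stats::uniroot(f, c(0.01, hi), tol = 1e-5)
  list(rho = sol$root, achieved = sol$f.root + cfg$latent_corr)
}

# Clinical-rate calibration ----------------------------------------------------

# mean of a normal(m, sd) truncated to [lo, hi]
truncnorm_mean <- function(m, sd, lo, hi) {
  a <- (lo - m) / sd; b <- (hi - m) / sd
  m + sd * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

# expected demographic part of the algorithm score for scored (operated,
# complete-input) respondents in one year: gender x environment x age factors
expected_demographic <- function(cfg, weights, year_idx) {
  e_gender <- weights$gender_female +
    (weights$gender_male - weights$gender_female) * cfg$male_prob
  u <- cfg$residence_probs[["urban"]] /
    (cfg$residence_probs[["urban"]] + cfg$residence_probs[["rural"]])
  e_env <- weights$env_rural + (weights$env_urban - weights$env_rural) * u
  tm <- truncnorm_mean(cfg$age_mean, cfg$age_sd,
                       cfg$age_range[1], cfg$age_range[2])
  wgt <- cfg$cell_counts[, year_idx] * cfg$surgery_prob[, year_idx]
  mean_age <- sum(wgt * tm) / sum(wgt)
  e_age <- weights$age_base + weights$age_slope * mean_age / 10
  e_gender * e_env * e_age
}

# per-year personalized-protocol/innovation adoption probability solved so
# the expected scored-population mean equals the published yearly trajectory.
# E[score] factorises (inputs independent given ward and year), leaving a
# quadratic in the adoption probability a:
#   (s1 + (p1-s1) a)(s2 + (p2-s2) a) = target / (demographic x fixed clinical)
calibrate_adoption <- function(cfg, weights = factor_weights()) {
  s1 <- weights$protocol_standard; p1 <- weights$protocol_personalized
  s2 <- weights$innovation_none;  p2 <- weights$innovation_used
  A <- (p1 - s1) * (p2 - s2)
  B <- s1 * (p2 - s2) + s2 * (p1 - s1)
  vapply(seq_along(cfg$years), function(j) {
    d <- expected_demographic(cfg, weights, j)
    fixed <- (weights$pain_base +
                weights$pain_slope * cfg$clinical$pain_mean[j]) *
      (weights$infection_no + (weights$infection_yes - weights$infection_no) *
         cfg$clinical$infection[j]) *
      (weights$complication_no +
         (weights$complication_yes - weights$complication_no) *
         cfg$clinical$complication[j])
    g <- cfg$score_targets[j] / (d * fixed)
    C <- s1 * s2 - g
    disc <- B^2 - 4 * A * C
    if (disc < 0) {
      warn(sprintf("score target for %d unreachable; adoption clamped",
                   cfg$years[j]), "postopsat_calibration_warning")
      return(1)
    }
    a <- (-B - sqrt(disc)) / (2 * A)
    if (a < 0 || a > 1) {
      warn(sprintf("score target for %d needs adoption %.2f; clamped",
                   cfg$years[j], a), "postopsat_calibration_warning")
      a <- min(max(a, 0), 1)
    }
    a
  }, numeric(1)) -> adoption
  stats::setNames(adoption, as.character(cfg$years))
}

# Generation -------------------------------------------------------------------

# complete (no-missingness) records for a ward x year count matrix
generate_complete <- function(cfg, counts, cells, rho) {
  n <- sum(counts)
  idx <- which(counts > 0, arr.ind = TRUE)
  ward_i <- rep(idx[, 1], counts[idx])
  year_i <- rep(idx[, 2], counts[idx])
  ord <- order(ward_i, year_i)
  ward_i <- ward_i[ord]; year_i <- year_i[ord]

  m <- cfg$age_mean[ward_i]
  lo <- stats::pnorm((cfg$age_range[1] - m) / cfg$age_sd)
  hi <- stats::pnorm((cfg$age_range[2] - m) / cfg$age_sd)
  age <- round(m + cfg$age_sd * stats::qnorm(lo + stats::runif(n) * (hi - lo)))

  gender <- ifelse(stats::runif(n) < cfg$male_prob, "male", "female")
  rp <- cfg$residence_probs
  residence <- sample(c("urban", "rural", NA), n, replace = TRUE, prob = rp)
  ep <- cfg$education_probs
  education <- sample(c(names(ep)[-length(ep)], NA), n, replace = TRUE,
                      prob = ep)
  operated <- stats::runif(n) < cfg$surgery_prob[cbind(ward_i, year_i)]
  q1 <- ifelse(operated, "yes", "no")

  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  q2 <- rep(NA_integer_, n)
  q3 <- rep(NA_integer_, n)
  cell_key <- (year_i - 1L) * nrow(counts) + ward_i
  for (k in unique(cell_key)) {
    rows <- which(cell_key == k)
    q3[rows] <- findInterval(z2[rows], cells$q3[[k]][[1]]) + 1L
    op <- rows[operated[rows]]
    if (length(op)) {
      q2[op] <- findInterval(z1[op], cells$q2[[k]][[1]]) + 1L
    }
  }

  cl <- cfg$clinical
  yes_no <- function(p) ifelse(stats::runif(n) < p, "yes", "no")
  infection <- yes_no(cl$infection[year_i])
  complication <- yes_no(cl$complication[year_i])
  protocol <- ifelse(stats::runif(n) < cl$adoption[year_i],
                     "personalized", "standard")
  innovation <- yes_no(cl$adoption[year_i])
  pain <- stats::rbinom(n, 10, cl$pain_mean[year_i] / 10)
  for (f in c("infection", "complication", "protocol", "innovation")) {
    v <- get(f); v[!operated] <- NA; assign(f, v)
  }
  pain[!operated] <- NA

  data.frame(year = cfg$years[year_i], ward = cfg$wards[ward_i],
             age = age, gender = gender, residence = residence,
             education = education, q1_surgery = q1,
             q2_postop_care = q2, q3_overall = q3,
             infection = infection, complication = complication,
             protocol = protocol, innovation = innovation, pain = pain,
             stringsAsFactors = FALSE)
}

# inject per-field non-response, then repair any well-formed record that the
# injection pushed over the exclusion threshold (restoring fields other than
# q2, whose non-response rate is a published quantity, and drawing values for
# structurally "no answer" education/residence only when unavoidable)
inject_missingness <- function(d, cfg) {
  mr <- cfg$missing_rate
  n <- nrow(d)
  kept <- d
  mask_field <- function(col, rate, only = rep(TRUE, n)) {
    hit <- only & stats::runif(n) < rate & !is.na(d[[col]])
    d[[col]][hit] <<- NA
  }
  operated <- !is.na(d$q1_surgery) & d$q1_surgery == "yes"
  mask_field("age", mr$age)
  mask_field("gender", mr$gender)
  mask_field("q3_overall", mr$q3_overall)
  mask_field("q2_postop_care", mr$q2_postop_care, operated)
  for (f in c("infection", "complication", "protocol", "innovation", "pain")) {
    mask_field(f, mr[[f]], operated)
  }

  threshold <- cfg$exclusion_threshold
  frac <- record_missingness(d)
  over <- which(frac > threshold)
  restore_order <- c("pain", "infection", "complication", "protocol",
                     "innovation", "age", "gender", "q3_overall")
  u <- cfg$residence_probs[["urban"]] /
    (cfg$residence_probs[["urban"]] + cfg$residence_probs[["rural"]])
  ep <- cfg$education_probs[-length(cfg$education_probs)]
  ep <- ep / sum(ep)
  for (i in over) {
    for (f in restore_order) {
      if (record_missingness(d[i, , drop = FALSE]) <= threshold) break
      if (is.na(d[[f]][i]) && !is.na(kept[[f]][i])) d[[f]][i] <- kept[[f]][i]
    }
    if (record_missingness(d[i, , drop = FALSE]) > threshold &&
        is.na(d$education[i])) {
      d$education[i] <- sample(names(ep), 1, prob = ep)
    }
    if (record_missingness(d[i, , drop = FALSE]) > threshold &&
        is.na(d$residence[i])) {
      d$residence[i] <- if (stats::runif(1) < u) "urban" else "rural"
    }
  }
  d
}

#' Generate a synthetic questionnaire cohort
#'
#' Deterministic given `config$seed`. Draws, for every ward-by-year cell, the
#' configured number of records (age truncated normal per ward; gender,
#' residence, education categorical; surgery Bernoulli; the two Likert items
#' by thresholding a correlated latent normal pair whose cutpoints are
#' calibrated per cell and whose correlation is calibrated so the pooled
#' mid-rank Spearman hits the target; clinical fields from the per-year
#' calibrated rates), injects field non-response, and appends the configured
#' number of grossly incomplete records. Well-formed records are guaranteed
#' to stay at or below the exclusion threshold, so [apply_exclusion()]
#' removes exactly the gross block.
#'
#' @param config a [default_config()]-style `synthetic_config`.
#' @return A [survey_dataset()] with attributes `config` and `calibration`
#'   (latent correlation used/achieved, implied cell means, clamped cells).
#' @export
generate_cohort <- function(config) {
  cfg <- validate_synthetic_config(config)
  cells <- calibrate_cells(cfg)
  if (length(cells$clamped)) {
    warn(paste0("likert targets clamped to (1, 5): ",
                paste(cells$clamped, collapse = "; ")),
         "postopsat_calibration_warning")
  }
  latent <- calibrate_latent_corr(cfg, cells)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  d <- generate_complete(cfg, cfg$cell_counts, cells, latent$rho)
  if (nrow(d)) d <- inject_missingness(d, cfg)

  n_gross <- cfg$gross_missing
  if (n_gross > 0) {
    pick <- sample(length(cfg$cell_counts), n_gross, replace = TRUE,
                   prob = as.vector(cfg$cell_counts))
    gcounts <- array(tabulate(pick, length(cfg$cell_counts)),
                     dim = dim(cfg$cell_counts),
                     dimnames = dimnames(cfg$cell_counts))
    g <- generate_complete(cfg, gcounts, cells, latent$rho)
    # blanking these five always pushes missingness over 20%, operated or not
    g[, c("age", "gender", "residence", "education", "q3_overall")] <- NA
    d <- rbind(d, g)
  }
  d <- d[sample(nrow(d)), , drop = FALSE]
  out <- survey_dataset(d, provenance = sprintf("synthetic(seed=%d)",
                                                cfg$seed))
  attr(out, "config") <- cfg
  attr(out, "calibration") <- list(
    latent_rho = latent$rho, spearman_achieved = latent$achieved,
    implied_q2 = cells$implied_q2, implied_q3 = cells$implied_q3,
    clamped = cells$clamped)
  out
}

# Parameter recovery ------------------------------------------------------------

#' Compare a generated cohort against its configuration
#'
#' Recovers the headline generator parameters from a cohort and checks each
#' against its configured (or calibration-implied) target with a tolerance of
#' three standard errors at the realized n (floored at 0.01 in absolute
#' value): male share, urban share among respondents with a residence answer,
#' ward mean ages (truncated-normal implied means), yearly surgery rates,
#' yearly means of both Likert items (implied by the calibrated cutpoints),
#' the pooled q2-q3 rank correlation (compared on the Fisher-z scale), and
#' the yearly mean algorithm scores of the exclusion-filtered cohort under
#' the default weights.
#'
#' @param dataset a cohort from [generate_cohort()].
#' @param config the `synthetic_config` it was generated from.
#' @return Data frame of class `recovery_report`: `parameter`, `target`,
#'   `estimate`, `error`, `tolerance`, `pass`.
#' @export
recovery_report <- function(dataset, config) {
  cfg <- validate_synthetic_config(config)
  d <- as.data.frame(dataset)
  cal <- attr(dataset, "calibration")
  if (is.null(cal)) {
    cells <- calibrate_cells(cfg)
    latent <- calibrate_latent_corr(cfg, cells)
    cal <- list(spearman_achieved = latent$achieved,
                implied_q2 = cells$implied_q2, implied_q3 = cells$implied_q3)
  }
  rows <- list()
  add <- function(parameter, target, estimate, se) {
    tol <- max(3 * se, 0.01)
    rows[[length(rows) + 1]] <<- data.frame(
      parameter = parameter, target = target, estimate = estimate,
      error = abs(estimate - target), tolerance = tol,
      pass = abs(estimate - target) <= tol, stringsAsFactors = FALSE)
  }
  share <- function(x, level) {
    x <- x[!is.na(x)]
    p <- mean(x == level)
    list(p = p, se = sqrt(p * (1 - p) / length(x)))
  }
  g <- share(d$gender, "male")
  add("male share", cfg$male_prob, g$p, g$se)
  r <- share(d$residence, "urban")
  add("urban share (answered)",
      cfg$residence_probs[["urban"]] /
        (cfg$residence_probs[["urban"]] + cfg$residence_probs[["rural"]]),
      r$p, r$se)
  tm <- truncnorm_mean(cfg$age_mean, cfg$age_sd,
                       cfg$age_range[1], cfg$age_range[2])
  for (w in cfg$wards) {
    a <- d$age[d$ward == w & !is.na(d$age)]
    add(paste0("mean age ", w), tm[[w]], mean(a),
        stats::sd(a) / sqrt(length(a)))
  }
  for (j in seq_along(cfg$years)) {
    y <- cfg$years[j]
    q1 <- d$q1_surgery[d$year == y & !is.na(d$q1_surgery)]
    target <- sum(cfg$cell_counts[, j] * cfg$surgery_prob[, j]) /
      sum(cfg$cell_counts[, j])
    s <- share(q1, "yes")
    add(paste0("surgery rate ", y), target, s$p, s$se)
  }
  for (q in c("q2_postop_care", "q3_overall")) {
    implied <- if (q == "q2_postop_care") cal$implied_q2 else cal$implied_q3
    wgt <- cfg$cell_counts * (if (q == "q2_postop_care") cfg$surgery_prob
                              else 1)
    for (j in seq_along(cfg$years)) {
      y <- cfg$years[j]
      v <- d[[q]][d$year == y & !is.na(d[[q]])]
      target <- sum(wgt[, j] * implied[, j]) / sum(wgt[, j])
      add(paste0(q, " mean ", y), target, mean(v),
          stats::sd(v) / sqrt(length(v)))
    }
  }
  ok <- !is.na(d$q2_postop_care) & !is.na(d$q3_overall)
  if (sum(ok) > 10) {
    sp <- spearman_rho(d$q2_postop_care[ok], d$q3_overall[ok])
    zt <- atanh(cal$spearman_achieved %||% cfg$latent_corr)
    ze <- atanh(sp$rho)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = "spearman q2~q3 (Fisher z)", target = zt, estimate = ze,
      error = abs(ze - zt), tolerance = 3 / sqrt(sp$n - 3),
      pass = abs(ze - zt) <= 3 / sqrt(sp$n - 3), stringsAsFactors = FALSE)
  }
  retained <- apply_exclusion(dataset, cfg$exclusion_threshold)$retained
  sc <- score_dataset(retained)
  for (j in seq_along(cfg$years)) {
    y <- cfg$years[j]
    v <- sc$total[sc$year == y]
    add(paste0("mean score ", y), unname(cfg$score_targets[j]), mean(v),
        stats::sd(v) / sqrt(length(v)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d of %d within tolerance\n",
              sum(x$pass), nrow(x)))
  df <- as.data.frame(x)
  for (f in c("target", "estimate", "error", "tolerance")) {
    df[[f]] <- signif(df[[f]], 4)
  }
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
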