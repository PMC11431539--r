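#' Factor weights for the satisfaction algorithm
#'
#' The composite satisfaction score is the product of eight factor values:
#' gender, age, environment (residence), infection, complication, care
#' protocol, innovative-product use, and pain. `factor_weights()` holds every
#' constant of that algorithm, plus the two interpretation thresholds. The
#' defaults are the published hospital calibration; sites with different
#' recovery profiles are expected to retune them (all arguments are plain
#' unitless multipliers).
#'
#' The score is inverse to satisfaction: larger totals mean lower
#' satisfaction. Bands: high satisfaction for total <= `high_threshold`
#' (default 1.5), moderate for totals up to `low_threshold` (default 3.0),
#' low above that.
#'
#' @param gender_male,gender_female multiplier by gender (defaults 1.2 / 1.0).
#' @param env_urban,env_rural multiplier by residence (defaults 1.3 / 1.0).
#' @param age_base,age_slope age factor is `age_base + age_slope * age / 10`,
#'   i.e. +0.1 per decade of age by default.
#' @param infection_yes,infection_no multiplier for postoperative infection
#'   (defaults 1.5 / 1.0).
#' @param complication_yes,complication_no multiplier for complications
#'   (defaults 2.0 / 1.0).
#' @param protocol_standard,protocol_personalized multiplier by care protocol
#'   (defaults 1.0 / 0.8; a personalized/innovative protocol lowers the score).
#' @param innovation_none,innovation_used multiplier for innovative products
#'   (defaults 1.0 / 0.9).
#' @param pain_base,pain_slope pain factor is `pain_base + pain_slope * pain`
#'   on the 0-10 numeric rating scale.
#' @param low_threshold,high_threshold category boundaries: total >
#'   `low_threshold` is "low" satisfaction, total <= `high_threshold` is
#'   "high", in between is "moderate". Must satisfy
#'   `high_threshold < low_threshold`.
#' @return An object of class `factor_weights` (a validated named list).
#' @examples
#' w <- factor_weights()
#' w$complication_yes  # 2.0
#' @export
factor_weights <- function(gender_male = 1.2, gender_female = 1.0,
                           env_urban = 1.3, env_rural = 1.0,
                           age_base = 1.0, age_slope = 0.1,
                           infection_yes = 1.5, infection_no = 1.0,
                           complication_yes = 2.0, complication_no = 1.0,
                           protocol_standard = 1.0, protocol_personalized = 0.8,
                           innovation_none = 1.0, innovation_used = 0.9,
                           pain_base = 1.0, pain_slope = 0.1,
                           low_threshold = 3.0, high_threshold = 1.5) {
  w <- list(
    gender_male = gender_male, gender_female = gender_female,
    env_urban = env_urban, env_rural = env_rural,
    age_base = age_base, age_slope = age_slope,
    infection_yes = infection_yes, infection_no = infection_no,
    complication_yes = complication_yes, complication_no = complication_no,
    protocol_standard = protocol_standard,
    protocol_personalized = protocol_personalized,
    innovation_none = innovation_none, innovation_used = innovation_used,
    pain_base = pain_base, pain_slope = pain_slope,
    low_threshold = low_threshold, high_threshold = high_threshold
  )
  validate_factor_weights(w)
}

validate_factor_weights <- function(w) {
  num <- vapply(w, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    abort(paste0("non-numeric weight field(s): ",
                 paste(names(w)[!num], collapse = ", ")),
          "postopsat_config_error")
  }
  positive <- setdiff(names(w), c("age_slope", "pain_slope"))
  bad <- positive[vapply(positive, function(f) w[[f]] <= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("weights must be strictly positive: ",
                 paste(bad, collapse = ", ")), "postopsat_config_error")
  }
  if (w$high_threshold >= w$low_threshold) {
    abort("high_threshold must be strictly below low_threshold",
          "postopsat_config_error")
  }
  structure(w, class = "factor_weights")
}

#' Read factor weights from a JSON configuration file
#'
#' The file holds a flat JSON object whose keys are the arguments of
#' [factor_weights()] (a top-level `"weights"` block is also accepted).
#' Missing keys keep their published defaults; unknown keys are an error.
#'
#' @param path path to a JSON file.
#' @return A `factor_weights` object.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("weights file not found: ", path), "postopsat_config_error")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$weights)) cfg <- cfg$weights
  unknown <- setdiff(names(cfg), names(formals(factor_weights)))
  if (length(unknown)) {
    abort(paste0("unknown weight field(s): ", paste(unknown, collapse = ", ")),
          "postopsat_config_error")
  }
  do.call(factor_weights, cfg)
}

#' @export
print.factor_weights <- function(x, ...) {
  cat("Satisfaction algorithm weights\n")
  cat(sprintf("  gender      male %.3g / female %.3g\n",
              x$gender_male, x$gender_female))
  cat(sprintf("  environment urban %.3g / rural %.3g\n",
              x$env_urban, x$env_rural))
  cat(sprintf("  age         %.3g + %.3g per decade\n", x$age_base, x$age_slope))
  cat(sprintf("  infection   yes %.3g / no %.3g\n",
              x$infection_yes, x$infection_no))
  cat(sprintf("  complication yes %.3g / no %.3g\n",
              x$complication_yes, x$complication_no))
  cat(sprintf("  protocol    standard %.3g / personalized %.3g\n",
              x$protocol_standard, x$protocol_personalized))
  cat(sprintf("  innovation  none %.3g / used %.3g\n",
              x$innovation_none, x$innovation_used))
  cat(sprintf("  pain        %.3g + %.3g per point (0-10)\n",
              x$pain_base, x$pain_slope))
  cat(sprintf("  bands       high <= %.3g < moderate <= %.3g < low\n",
              x$high_threshold, x$low_threshold))
  invisible(x)
}
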