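# Study configuration: eligibility geography, point values, thresholds.

#' Fraud criterion identifiers
#'
#' The eight rule-based criteria, in canonical reporting order. Point
#' values are carried by the study configuration; the defaults (six
#' 1-point criteria and two 2-point criteria) span a 0-10 scale.
#'
#' @return Character vector of the eight criterion ids.
#' @export
criterion_ids <- function() {
  c("geolocation", "phone", "name_mismatch", "email_pattern",
    "dup_name_plus_item", "dup_two_items", "dup_dob_plus_item",
    "short_duration")
}

default_point_values <- function() {
  c(geolocation = 1L, phone = 1L, name_mismatch = 1L, email_pattern = 1L,
    dup_two_items = 1L, dup_name_plus_item = 2L, dup_dob_plus_item = 2L,
    short_duration = 1L)
}

#' Define a study area for geographic eligibility
#'
#' A study area is a country, a subnational state code, and a set of
#' eligible county names. County membership tests are case-insensitive.
#'
#' @param country Country code (e.g. `"US"`).
#' @param state Subnational state code (e.g. `"KY"`).
#' @param counties Character vector of eligible county names (non-empty).
#' @return An object of class `study_area`.
#' @export
study_area <- function(country, state, counties) {
  stopifnot(is.character(country), length(country) == 1L,
            is.character(state), length(state) == 1L)
  counties <- unique(as.character(counties))
  if (length(counties) == 0L) {
    abort("`counties` must contain at least one eligible county.")
  }
  structure(
    list(country = country, state = state, counties = counties),
    class = "study_area"
  )
}

#' @export
print.study_area <- function(x, ...) {
  cat("<study_area> ", x$country, "/", x$state, ", ",
      length(x$counties), " eligible counties\n", sep = "")
  invisible(x)
}

#' The default Central Kentucky study area
#'
#' Fifteen Bluegrass-region counties used as the default eligibility
#' geography throughout the package (and by the canonical fixture).
#'
#' @return A [study_area()] object.
#' @export
central_ky_study_area <- function() {
  study_area(
    country = "US", state = "KY",
    counties = c("Anderson", "Bourbon", "Boyle", "Clark", "Fayette",
                 "Franklin", "Garrard", "Harrison", "Jessamine",
                 "Lincoln", "Madison", "Mercer", "Nicholas", "Scott",
                 "Woodford")
  )
}

#' Build a study configuration
#'
#' Bundles the eligibility geography, per-criterion point values,
#' categorization thresholds, and numeric cutoffs used by the scoring
#' engine. Defaults reproduce the published protocol: 1 point for
#' possibly-explainable signals, 2 points for signals treated as
#' independently indicative of fraud, a fraud threshold of 2 total
#' points, a potential-fraud score of exactly 1, a 50% completeness
#' inclusion floor, a 5-minute minimum survey duration, and a minimum of
#' 3 letter/digit alternations for the suspicious-email heuristic.
#'
#' @param study_area A [study_area()]; defaults to
#'   [central_ky_study_area()].
#' @param point_values Named integer vector over [criterion_ids()].
#' @param fraud_threshold Total points at or above which an entry is
#'   categorized as fraud.
#' @param potential_threshold Total points at or above which (but below
#'   `fraud_threshold`) an entry is potential fraud.
#' @param completeness_min Minimum completeness fraction (inclusive) for
#'   an entry to be evaluable.
#' @param min_duration_minutes Survey durations strictly below this are
#'   flagged by the duration criterion.
#' @param email_alternation_min Minimum number of letter/digit run
#'   transitions in an email local part for the pattern criterion.
#' @return An object of class `study_config`.
#' @export
study_config <- function(study_area = central_ky_study_area(),
                         point_values = default_point_values(),
                         fraud_threshold = 2L,
                         potential_threshold = 1L,
                         completeness_min = 0.5,
                         min_duration_minutes = 5,
                         email_alternation_min = 3L) {
  defaults <- default_point_values()
  pv <- defaults
  pv[names(point_values)] <- as.integer(point_values)
  unknown <- setdiff(names(point_values), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown criterion in `point_values`: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(pv %in% 1:2)) {
    abort("Point values must be 1 or 2.")
  }
  fraud_threshold <- as.integer(fraud_threshold)
  potential_threshold <- as.integer(potential_threshold)
  if (!(fraud_threshold > potential_threshold && potential_threshold > 0L)) {
    abort("Need fraud_threshold > potential_threshold > 0.")
  }
  stopifnot(inherits(study_area, "study_area"),
            completeness_min >= 0, completeness_min <= 1,
            min_duration_minutes > 0, email_alternation_min >= 1)
  structure(
    list(study_area = study_area,
         point_values = pv,
         fraud_threshold = fraud_threshold,
         potential_threshold = potential_threshold,
         completeness_min = completeness_min,
         min_duration_minutes = min_duration_minutes,
         email_alternation_min = as.integer(email_alternation_min)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat("  area: ", x$study_area$country, "/", x$study_area$state, " (",
      length(x$study_area$counties), " counties)\n", sep = "")
  cat("  points:", paste(names(x$point_values), x$point_values,
                         sep = "=", collapse = " "), "\n")
  cat("  thresholds: fraud >=", x$fraud_threshold,
      "; potential =", x$potential_threshold, "\n")
  cat("  completeness_min:", x$completeness_min,
      " min_duration_minutes:", x$min_duration_minutes,
      " email_alternation_min:", x$email_alternation_min, "\n")
  invisible(x)
}

#' Read a study configuration from JSON or YAML
#'
#' Any field omitted from the file keeps its [study_config()] default.
#' The study area is given as a nested object with `country`, `state`
#' and `counties` fields.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A [study_config()].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such config file: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  area <- if (!is.null(raw$study_area)) {
    study_area(raw$study_area$country, raw$study_area$state,
               unlist(raw$study_area$counties))
  } else {
    central_ky_study_area()
  }
  args <- raw[intersect(names(raw),
                        c("point_values", "fraud_threshold",
                          "potential_threshold", "completeness_min",
                          "min_duration_minutes", "email_alternation_min"))]
  if (!is.null(args$point_values)) {
    args$point_values <- unlist(args$point_values)
  }
  do.call(study_config, c(list(study_area = area), args))
}

#' Write a study configuration to JSON
#'
#' @param config A [study_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  out <- list(
    study_area = list(country = config$study_area$country,
                      state = config$study_area$state,
                      counties = config$study_area$counties),
    point_values = as.list(config$point_values),
    fraud_threshold = config$fraud_threshold,
    potential_threshold = config$potential_threshold,
    completeness_min = config$completeness_min,
    min_duration_minutes = config$min_duration_minutes,
    email_alternation_min = config$email_alternation_min
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
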