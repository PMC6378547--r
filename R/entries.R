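# CSV ingest of survey entries and the completeness inclusion filter.

entry_columns <- function() {
  c("entry_id", "submitted_at", "screening_start", "screening_end",
    "consent_start", "consent_end", "survey_start", "survey_end",
    "completeness", "ip_address", "geo_country", "geo_state",
    "geo_county", "name_consent", "name_contact", "name_incentive",
    "email", "phone", "date_of_birth", "mail_street", "mail_city",
    "mail_county", "mail_state", "mail_country", "incentive_method",
    "event_participation", "scripted_response")
}

timestamp_columns <- function() {
  c("submitted_at", "screening_start", "screening_end", "consent_start",
    "consent_end", "survey_start", "survey_end")
}

incentive_levels <- function() c("egift", "mail", "in_person", "declined")
scripted_levels <- function() c("none", "verified", "admitted_ineligible",
                                "failed_verification")

blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  x
}

parse_field <- function(x, field, parser, what) {
  parsed <- suppressWarnings(parser(x))
  bad <- which(!is.na(x) & is.na(parsed))
  if (length(bad)) {
    abort(paste0("Malformed ", what, " in field `", field, "` at row ",
                 bad[1L], ": \"", x[bad[1L]], "\""))
  }
  parsed
}

parse_ts_vec <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S")) {
    need <- is.na(out) & !is.na(x)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = "UTC"))
  }
  out
}

parse_ts <- function(x, field) {
  parse_field(x, field, parse_ts_vec, "timestamp")
}

#' Read survey entries from CSV
#'
#' Reads the documented one-row-per-entry schema, validates every field,
#' and returns entries sorted by submission time (ties broken by
#' `entry_id`). Blank cells become missing values. Malformed rows and
#' duplicate entry ids are errors naming the offending row.
#'
#' @param path Path to an entries CSV (see [entry_columns()] for the
#'   header).
#' @param config A [study_config()] (reserved for schema options;
#'   defaults are fine).
#' @return A tibble of survey entries, one row per entry.
#' @export
read_entries <- function(path, config = study_config()) {
  if (!file.exists(path)) abort(paste0("No such entries file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(entry_columns(), names(raw))
  if (length(missing_cols)) {
    abort(paste0("Entries file is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- raw[entry_columns()]
  raw[] <- lapply(raw, blank_to_na)
  as_entries(raw)
}

# Validate + type a character-mode entries table.
as_entries <- function(raw) {
  entries <- tibble::as_tibble(raw)
  if (nrow(entries) == 0L) {
    entries <- entries |>
      mutate(across(dplyr::all_of(timestamp_columns()),
                    ~ as.POSIXct(character(0), tz = "UTC")),
             completeness = double(0),
             date_of_birth = as.Date(character(0)),
             event_participation = logical(0))
    return(entries)
  }
  if (anyNA(entries$entry_id)) {
    abort(paste0("Missing entry_id at row ",
                 which(is.na(entries$entry_id))[1L]))
  }
  dup <- duplicated(entries$entry_id)
  if (any(dup)) {
    abort(paste0("Duplicate entry_id \"", entries$entry_id[dup][1L],
                 "\" at row ", which(dup)[1L]))
  }
  for (col in timestamp_columns()) {
    entries[[col]] <- parse_ts(entries[[col]], col)
  }
  if (anyNA(entries$submitted_at)) {
    abort(paste0("Missing submitted_at at row ",
                 which(is.na(entries$submitted_at))[1L]))
  }
  entries$completeness <- parse_field(entries$completeness, "completeness",
                                      as.numeric, "number")
  bad <- which(is.na(entries$completeness) | entries$completeness < 0 |
                 entries$completeness > 1)
  if (length(bad)) {
    abort(paste0("completeness must be in [0, 1] at row ", bad[1L]))
  }
  entries$date_of_birth <- parse_field(entries$date_of_birth,
                                       "date_of_birth",
                                       function(v) as.Date(v, "%Y-%m-%d"),
                                       "date")
  entries$incentive_method[is.na(entries$incentive_method)] <- "egift"
  bad <- which(!entries$incentive_method %in% incentive_levels())
  if (length(bad)) {
    abort(paste0("Unknown incentive_method \"",
                 entries$incentive_method[bad[1L]], "\" at row ", bad[1L]))
  }
  ev <- toupper(entries$event_participation)
  ev[is.na(ev)] <- "FALSE"
  bad <- which(!ev %in% c("TRUE", "FALSE"))
  if (length(bad)) {
    abort(paste0("event_participation must be TRUE/FALSE at row ", bad[1L]))
  }
  entries$event_participation <- ev == "TRUE"
  entries$scripted_response[is.na(entries$scripted_response)] <- "none"
  bad <- which(!entries$scripted_response %in% scripted_levels())
  if (length(bad)) {
    abort(paste0("Unknown scripted_response \"",
                 entries$scripted_response[bad[1L]], "\" at row ", bad[1L]))
  }
  for (sec in c("screening", "consent", "survey")) {
    s <- entries[[paste0(sec, "_start")]]
    e <- entries[[paste0(sec, "_end")]]
    bad <- which(!is.na(s) & !is.na(e) & e < s)
    if (length(bad)) {
      abort(paste0(sec, " section ends before it starts at row ", bad[1L]))
    }
  }
  bad <- which(entries$incentive_method == "mail" &
                 is.na(entries$mail_county))
  if (length(bad)) {
    abort(paste0("Mailed incentive without a mailing address at row ",
                 bad[1L]))
  }
  entries |> arrange(.data$submitted_at, .data$entry_id)
}

#' Write survey entries to CSV
#'
#' Inverse of [read_entries()]: timestamps are written as ISO-8601 UTC
#' and missing optionals as blank cells, so a write/read round trip is
#' the identity.
#'
#' @param entries Entries tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_entries <- function(entries, path) {
  out <- entries[entry_columns()]
  for (col in timestamp_columns()) {
    out[[col]] <- format(out[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  out$date_of_birth <- format(out$date_of_birth, "%Y-%m-%d")
  out$event_participation <- ifelse(out$event_participation, "TRUE", "FALSE")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Keep entries meeting the completeness inclusion floor
#'
#' Retains exactly the entries with `completeness >=
#' config$completeness_min` (inclusive boundary), preserving order. The
#' number of dropped entries is reported and recorded in attributes
#' `n_input`, `n_kept` and `n_dropped` on the result.
#'
#' @param entries Entries tibble.
#' @param config A [study_config()].
#' @param quiet Suppress the informational message.
#' @return The filtered tibble.
#' @export
filter_completeness <- function(entries, config = study_config(),
                                quiet = FALSE) {
  keep <- entries$completeness >= config$completeness_min
  out <- entries[keep, , drop = FALSE]
  attr(out, "n_input") <- nrow(entries)
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  if (!quiet) {
    inform(paste0("filter_completeness: kept ", sum(keep), " of ",
                  nrow(entries), " entries (dropped ", sum(!keep),
                  " below ", config$completeness_min, ")"))
  }
  out
}

#' Read an offline phone directory
#'
#' Two-column CSV (`phone`, `line_type`) standing in for a live
#' reverse-lookup service. Phone numbers are normalized on read; line
#' types are `personal`, `business_or_org` or `invalid`.
#'
#' @param path Path to the directory CSV.
#' @return A `phone_directory` tibble.
#' @export
read_phone_directory <- function(path) {
  if (!file.exists(path)) abort(paste0("No such directory file: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("phone", "line_type") %in% names(raw))) {
    abort("Phone directory needs columns `phone` and `line_type`.")
  }
  phone_directory(raw$phone, raw$line_type)
}

#' Construct a phone directory in memory
#'
#' @param phone Character vector of phone numbers.
#' @param line_type Matching vector of line types (`personal`,
#'   `business_or_org`, `invalid`).
#' @return A `phone_directory` tibble with normalized numbers.
#' @export
phone_directory <- function(phone = character(0),
                            line_type = character(0)) {
  bad <- setdiff(unique(line_type),
                 c("personal", "business_or_org", "invalid"))
  if (length(bad)) {
    abort(paste0("Unknown line_type: ", paste(bad, collapse = ", ")))
  }
  out <- tibble(phone = normalize_phone(phone), line_type = line_type)
  out <- out[!is.na(out$phone), ]
  out <- out[!duplicated(out$phone), ]
  class(out) <- c("phone_directory", class(out))
  out
}

#' Write a phone directory to CSV
#'
#' @param directory A [phone_directory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phone_directory <- function(directory, path) {
  readr::write_csv(tibble(phone = directory$phone,
                          line_type = directory$line_type), path)
  invisible(path)
}

#' Look up line types for phone numbers
#'
#' Closed-world lookup: a number absent from the directory is reported
#' as `invalid`; a missing number stays `NA`.
#'
#' @param directory A [phone_directory()].
#' @param phone Character vector of phone numbers (raw; normalized
#'   internally).
#' @return Character vector of line types.
#' @export
phone_line_type <- function(directory, phone) {
  norm <- normalize_phone(phone)
  idx <- match(norm, directory$phone)
  out <- directory$line_type[idx]
  out[is.na(out) & !is.na(norm)] <- "invalid"
  out
}
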