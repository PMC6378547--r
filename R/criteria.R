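# The eight-criterion scoring engine. Each eval_* function is
# vectorized over an entries tibble and returns one row per entry with
# a status (violated / clear / not_evaluable), the points awarded, and
# a human-readable evidence string.

criterion_result <- function(entries, criterion, status, points,
                             evidence = "", ...) {
  tibble(entry_id = entries$entry_id, criterion = criterion,
         status = status, points = as.integer(points),
         evidence = evidence, ...)
}

# Raw out-of-area test at the estimate's stated resolution. Benefit of
# the doubt at coarse resolution: a country/state match with no deeper
# information is treated as inside the area. NA when no geolocation at
# all is available.
geo_out_of_area <- function(entries, area) {
  country <- entries$geo_country
  state <- entries$geo_state
  county <- entries$geo_county
  out <- rep(NA, nrow(entries))
  has_geo <- !is.na(country) | !is.na(state) | !is.na(county)
  out[has_geo] <- FALSE
  bad_country <- has_geo & (is.na(country) | country != area$country)
  out[bad_country] <- TRUE
  check_state <- has_geo & !bad_country & !is.na(state)
  out[check_state & state != area$state] <- TRUE
  check_county <- has_geo & !bad_country & !is.na(state) &
    state == area$state & !is.na(county)
  out[check_county &
        !(tolower(county) %in% tolower(area$counties))] <- TRUE
  out
}

# Location eligibility established independently of GeoIP: observed
# participation at a recruitment event, or a mailed incentive going to
# an address inside the study area.
geo_override <- function(entries, area) {
  mail_ok <- entries$incentive_method == "mail" &
    !is.na(entries$mail_county) &
    tolower(entries$mail_county) %in% tolower(area$counties) &
    (is.na(entries$mail_state) | entries$mail_state == area$state) &
    (is.na(entries$mail_country) | entries$mail_country == area$country)
  list(event = entries$event_participation, mail = mail_ok)
}

#' Evaluate the geolocation criterion
#'
#' An entry violates the criterion when its IP-derived location estimate
#' falls outside the study area *and* neither override applies. The
#' overrides come first: observed participation at a recruitment event,
#' or a mailed incentive addressed inside the study area, establish
#' eligibility regardless of the GeoIP estimate. Estimates are trusted
#' at their stated resolution, so a matching state with no county
#' information is treated as inside the area.
#'
#' @param entries Entries tibble.
#' @param area A [study_area()].
#' @param config A [study_config()] supplying the point value.
#' @return A tibble with one row per entry: `entry_id`, `criterion`,
#'   `status`, `points`, `evidence`, and a logical `raw_out_of_area`
#'   column giving the pre-override location test.
#' @export
eval_geolocation <- function(entries, area = central_ky_study_area(),
                             config = study_config(study_area = area)) {
  raw_out <- geo_out_of_area(entries, area)
  ov <- geo_override(entries, area)
  status <- rep("clear", nrow(entries))
  status[is.na(raw_out)] <- "not_evaluable"
  status[!is.na(raw_out) & raw_out] <- "violated"
  status[(ov$event | ov$mail) & status == "violated"] <- "clear"
  evidence <- rep("", nrow(entries))
  evidence[!is.na(raw_out) & raw_out & ov$event] <- "override:event"
  evidence[!is.na(raw_out) & raw_out & !ov$event & ov$mail] <-
    "override:mail_address"
  viol <- status == "violated"
  evidence[viol] <- paste0(
    "geo:", entries$geo_country[viol], "/",
    ifelse(is.na(entries$geo_state[viol]), "?", entries$geo_state[viol]),
    "/",
    ifelse(is.na(entries$geo_county[viol]), "?", entries$geo_county[viol]))
  pts <- ifelse(viol, config$point_values[["geolocation"]], 0L)
  criterion_result(entries, "geolocation", status, pts, evidence,
                   raw_out_of_area = raw_out)
}

#' Evaluate the phone criterion
#'
#' Violated when the (normalized) phone number maps to a business or
#' organization line or is invalid under the closed-world offline
#' directory; clear when it maps to a personal line; not evaluable when
#' no phone number was given.
#'
#' @param entries Entries tibble.
#' @param directory A [phone_directory()].
#' @param config A [study_config()].
#' @return Per-entry criterion results (see [eval_geolocation()]).
#' @export
eval_phone <- function(entries, directory, config = study_config()) {
  type <- phone_line_type(directory, entries$phone)
  status <- dplyr::case_when(
    is.na(type) ~ "not_evaluable",
    type == "personal" ~ "clear",
    TRUE ~ "violated"
  )
  pts <- ifelse(status == "violated", config$point_values[["phone"]], 0L)
  evidence <- ifelse(status == "violated", paste0("line_type:", type), "")
  criterion_result(entries, "phone", status, pts, evidence)
}

#' Extract the normalized name token-sets of an entry
#'
#' Collects the consent, contact and incentive name fields plus a
#' candidate name parsed from the email local part (split on `.`, `_`,
#' `-` and digit runs; alphabetic tokens of length >= 2). Each source
#' becomes a lowercase token set with punctuation stripped; empty
#' sources are dropped.
#'
#' @param entry A one-row entries tibble (or list with the name/email
#'   fields).
#' @return A named list of character vectors (token sets), possibly
#'   empty.
#' @export
extract_names <- function(entry) {
  sources <- list(
    name_consent = name_tokens(entry$name_consent[[1]]),
    name_contact = name_tokens(entry$name_contact[[1]]),
    name_incentive = name_tokens(entry$name_incentive[[1]]),
    email = email_name_candidate(entry$email[[1]])
  )
  sources[vapply(sources, length, integer(1)) > 0L]
}

#' Evaluate within-entry name consistency
#'
#' Cross-references the up-to-three explicit name fields and the
#' email-derived candidate name. With fewer than two non-empty sources
#' the criterion is not evaluable; otherwise it is violated when some
#' pair of sources shares no token at all (plain token-set comparison;
#' no phonetic or nickname matching).
#'
#' @inheritParams eval_phone
#' @return Per-entry criterion results.
#' @export
eval_name_consistency <- function(entries, config = study_config()) {
  res <- purrr::map(seq_len(nrow(entries)), function(i) {
    sources <- extract_names(entries[i, ])
    if (length(sources) < 2L) {
      return(list(status = "not_evaluable", evidence = ""))
    }
    pairs <- utils::combn(length(sources), 2L, simplify = FALSE)
    for (p in pairs) {
      a <- sources[[p[1L]]]
      b <- sources[[p[2L]]]
      if (length(intersect(a, b)) == 0L) {
        return(list(status = "violated",
                    evidence = paste0(names(sources)[p[1L]], "=\"",
                                      paste(a, collapse = " "), "\" vs ",
                                      names(sources)[p[2L]], "=\"",
                                      paste(b, collapse = " "), "\"")))
      }
    }
    list(status = "clear", evidence = "")
  })
  status <- vapply(res, `[[`, character(1), "status")
  evidence <- vapply(res, `[[`, character(1), "evidence")
  pts <- ifelse(status == "violated",
                config$point_values[["name_mismatch"]], 0L)
  criterion_result(entries, "name_mismatch", status, pts, evidence)
}

#' Evaluate the suspicious email-pattern criterion
#'
#' Operationalizes the bot-style address heuristic: the local part is
#' segmented into maximal letter runs and digit runs; the entry is
#' flagged when the number of run transitions reaches
#' `config$email_alternation_min` (default 3) *and* no alphabetic run of
#' length >= 3 matches a token of the entry's explicit name fields
#' (addresses that still contain the respondent's name are not
#' penalized).
#'
#' @inheritParams eval_phone
#' @return Per-entry criterion results.
#' @export
eval_email_pattern <- function(entries, config = study_config()) {
  res <- purrr::map(seq_len(nrow(entries)), function(i) {
    email <- entries$email[i]
    if (is.na(email) || trimws(email) == "") {
      return(list(status = "not_evaluable", evidence = ""))
    }
    trans <- email_alternations(email)
    if (is.na(trans) || trans < config$email_alternation_min) {
      return(list(status = "clear", evidence = ""))
    }
    own <- unique(c(name_tokens(entries$name_consent[i]),
                    name_tokens(entries$name_contact[i]),
                    name_tokens(entries$name_incentive[i])))
    runs <- email_letter_runs(email)
    namelike <- runs[nchar(runs) >= 3L & runs %in% own]
    if (length(namelike)) {
      return(list(status = "clear",
                  evidence = paste0("name_run:", namelike[1L])))
    }
    list(status = "violated",
         evidence = paste0("alternations:", trans))
  })
  status <- vapply(res, `[[`, character(1), "status")
  evidence <- vapply(res, `[[`, character(1), "evidence")
  pts <- ifelse(status == "violated",
                config$point_values[["email_pattern"]], 0L)
  criterion_result(entries, "email_pattern", status, pts, evidence)
}

#' Evaluate the survey-duration criterion
#'
#' Violated when the survey section (only; screening and consent do not
#' count) was completed in strictly less than
#' `config$min_duration_minutes` minutes. Exactly the threshold is
#' clear. Not evaluable when either survey timestamp is missing.
#'
#' @inheritParams eval_phone
#' @return Per-entry criterion results.
#' @export
eval_duration <- function(entries, config = study_config()) {
  mins <- as.numeric(difftime(entries$survey_end, entries$survey_start,
                              units = "mins"))
  status <- dplyr::case_when(
    is.na(mins) ~ "not_evaluable",
    mins < config$min_duration_minutes ~ "violated",
    TRUE ~ "clear"
  )
  pts <- ifelse(status == "violated",
                config$point_values[["short_duration"]], 0L)
  evidence <- ifelse(status == "violated",
                     paste0("duration_min:", round(mins, 2)), "")
  criterion_result(entries, "short_duration", status, pts, evidence)
}

# Canonical string keys for the explicit-name token sets of each entry
# (email-derived candidates are not used for cross-entry name matching).
entry_name_keys <- function(entries) {
  purrr::map(seq_len(nrow(entries)), function(i) {
    keys <- c(paste(name_tokens(entries$name_consent[i]), collapse = " "),
              paste(name_tokens(entries$name_contact[i]), collapse = " "),
              paste(name_tokens(entries$name_incentive[i]), collapse = " "))
    unique(keys[keys != ""])
  })
}

#' Evaluate the three cross-entry duplicate rules
#'
#' Matches the contact items (phone, email, mailing address, each
#' normalized) of every entry against all chronologically prior entries
#' (rows must be sorted by submission time). Three independent rules,
#' each firing at most once per entry and each requiring a *single*
#' prior entry to supply all of its elements:
#'
#' * `dup_two_items` (1 point): two or more contact items match one
#'   prior entry;
#' * `dup_name_plus_item` (2 points): a first-and-last-name token set
#'   matches and at least one item matches one prior entry;
#' * `dup_dob_plus_item` (2 points): the date of birth matches and at
#'   least one item matches one prior entry.
#'
#' A missing field never matches. The rules may fire against different
#' prior entries and their points sum. Not-evaluable bookkeeping follows
#' each rule's distinctive evidence: all three items absent
#' (`dup_two_items`), no name fields (`dup_name_plus_item`), no date of
#' birth (`dup_dob_plus_item`).
#'
#' @inheritParams eval_phone
#' @return A tibble with three rows per entry (one per rule).
#' @export
eval_cross_entry <- function(entries, config = study_config()) {
  n <- nrow(entries)
  ph <- normalize_phone(entries$phone)
  em <- normalize_email(entries$email)
  ad <- normalize_address(entries$mail_street, entries$mail_city,
                          entries$mail_county)
  if (n == 0L) ad <- character(0)
  dob <- entries$date_of_birth
  keys <- entry_name_keys(entries)
  has_name <- vapply(keys, length, integer(1)) > 0L
  n_items <- (!is.na(ph)) + (!is.na(em)) + (!is.na(ad))

  rules <- c("dup_two_items", "dup_name_plus_item", "dup_dob_plus_item")
  status <- matrix("clear", nrow = n, ncol = 3L,
                   dimnames = list(NULL, rules))
  evidence <- matrix("", nrow = n, ncol = 3L,
                     dimnames = list(NULL, rules))
  status[n_items == 0L, "dup_two_items"] <- "not_evaluable"
  status[!has_name, "dup_name_plus_item"] <- "not_evaluable"
  status[is.na(dob), "dup_dob_plus_item"] <- "not_evaluable"

  for (i in seq_len(n)[-1]) {
    j <- seq_len(i - 1L)
    matches <- (!is.na(ph[i]) & !is.na(ph[j]) & ph[j] == ph[i]) +
      (!is.na(em[i]) & !is.na(em[j]) & em[j] == em[i]) +
      (!is.na(ad[i]) & !is.na(ad[j]) & ad[j] == ad[i])
    hit <- which(matches >= 1L)
    if (length(hit) == 0L) next
    two <- hit[matches[hit] >= 2L]
    if (length(two) && status[i, "dup_two_items"] == "clear") {
      status[i, "dup_two_items"] <- "violated"
      evidence[i, "dup_two_items"] <-
        paste0("prior:", entries$entry_id[two[1L]])
    }
    if (status[i, "dup_name_plus_item"] == "clear") {
      nm <- hit[vapply(hit, function(k) {
        any(keys[[k]] %in% keys[[i]])
      }, logical(1))]
      if (length(nm)) {
        status[i, "dup_name_plus_item"] <- "violated"
        evidence[i, "dup_name_plus_item"] <-
          paste0("prior:", entries$entry_id[nm[1L]])
      }
    }
    if (!is.na(dob[i]) && status[i, "dup_dob_plus_item"] == "clear") {
      db <- hit[!is.na(dob[hit]) & dob[hit] == dob[i]]
      if (length(db)) {
        status[i, "dup_dob_plus_item"] <- "violated"
        evidence[i, "dup_dob_plus_item"] <-
          paste0("prior:", entries$entry_id[db[1L]])
      }
    }
  }

  purrr::map_dfr(rules, function(r) {
    pts <- ifelse(status[, r] == "violated",
                  config$point_values[[r]], 0L)
    criterion_result(entries, r, status[, r], pts, evidence[, r])
  }) |> arrange(match(.data$entry_id, entries$entry_id))
}

#' Score all entries against the eight criteria
#'
#' Runs every criterion evaluation (cross-entry rules against all
#' chronologically prior entries) and assembles one scorecard per entry.
#' Not-evaluable criteria contribute zero points; totals lie in 0-10
#' under the default point values.
#'
#' @param entries Entries tibble (evaluable entries; sorted internally
#'   by submission time).
#' @param config A [study_config()].
#' @param area A [study_area()]; defaults to the one in `config`.
#' @param directory A [phone_directory()].
#' @return A wide tibble with one row per entry: `entry_id`,
#'   `<criterion>_status` and `<criterion>_points` for each of the eight
#'   criteria, and `total`. The long per-criterion results (including
#'   evidence strings and the raw geolocation flag) are attached as
#'   attribute `"long"`.
#' @export
score_entries <- function(entries, config = study_config(),
                          area = config$study_area,
                          directory = phone_directory()) {
  entries <- entries |> arrange(.data$submitted_at, .data$entry_id)
  if (nrow(entries) == 0L) {
    wide <- tibble(entry_id = character(0))
    for (cr in criterion_ids()) {
      wide[[paste0(cr, "_status")]] <- character(0)
      wide[[paste0(cr, "_points")]] <- integer(0)
    }
    wide$total <- numeric(0)
    attr(wide, "long") <- criterion_result(entries, character(0),
                                           character(0), integer(0))
    attr(wide, "raw_out_of_area") <- logical(0)
    class(wide) <- c("scorecards", class(wide))
    return(wide)
  }
  long <- bind_rows(
    eval_geolocation(entries, area, config) |>
      select(-"raw_out_of_area"),
    eval_phone(entries, directory, config),
    eval_name_consistency(entries, config),
    eval_email_pattern(entries, config),
    eval_cross_entry(entries, config),
    eval_duration(entries, config)
  )
  geo <- eval_geolocation(entries, area, config)
  wide <- long |>
    select("entry_id", "criterion", "status", "points") |>
    tidyr::pivot_wider(names_from = "criterion",
                       values_from = c("status", "points"),
                       names_glue = "{criterion}_{.value}")
  wide$total <- rowSums(wide[paste0(criterion_ids(), "_points")])
  wide <- wide[c("entry_id",
                 as.vector(rbind(paste0(criterion_ids(), "_status"),
                                 paste0(criterion_ids(), "_points"))),
                 "total")]
  wide <- wide[match(entries$entry_id, wide$entry_id), ]
  attr(wide, "long") <- long
  attr(wide, "raw_out_of_area") <-
    setNames(geo$raw_out_of_area, geo$entry_id)
  class(wide) <- c("scorecards", class(wide))
  wide
}

#' Score a single entry against its prior entries
#'
#' Convenience wrapper around [score_entries()] honoring the
#' prior-entry semantics of the cross-entry rules: `prior` must contain
#' only entries submitted at or before `entry`.
#'
#' @param entry One-row entries tibble.
#' @param prior Entries tibble of chronologically prior entries (may be
#'   empty).
#' @inheritParams score_entries
#' @return A one-row scorecard tibble.
#' @export
score_entry <- function(entry, prior = entry[0, ],
                        config = study_config(),
                        area = config$study_area,
                        directory = phone_directory()) {
  stopifnot(nrow(entry) == 1L)
  if (nrow(prior) && any(prior$submitted_at > entry$submitted_at)) {
    abort("`prior` must only contain entries submitted before `entry`.")
  }
  cards <- score_entries(bind_rows(prior, entry), config, area, directory)
  out <- cards[cards$entry_id == entry$entry_id, ]
  attr(out, "long") <- NULL
  out
}

#' Write scorecards to CSV
#'
#' @param scorecards Result of [score_entries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorecards <- function(scorecards, path) {
  out <- scorecards
  attr(out, "long") <- NULL
  attr(out, "raw_out_of_area") <- NULL
  readr::write_csv(as_tibble(out), path)
  invisible(path)
}
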