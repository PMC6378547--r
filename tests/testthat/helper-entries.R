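# Programmatic micro-fixtures for unit tests.

test_area <- function() central_ky_study_area()

test_directory <- function() {
  phone_directory(
    phone = c("8595550100", "8595550101", "8595550102", "8595550103",
              "8595559900"),
    line_type = c("personal", "personal", "personal", "personal",
                  "business_or_org")
  )
}

# One survey entry with sensible clean defaults; any field can be
# overridden. `minutes` sets the survey-section duration.
make_entry <- function(entry_id = "E001",
                       submitted = "2020-01-01 10:00:00",
                       minutes = 15, completeness = 1,
                       ...) {
  submitted_at <- as.POSIXct(submitted, tz = "UTC")
  survey_start <- submitted_at - minutes * 60
  entry <- tibble::tibble(
    entry_id = entry_id,
    submitted_at = submitted_at,
    screening_start = survey_start - 420,
    screening_end = survey_start - 180,
    consent_start = survey_start - 180,
    consent_end = survey_start,
    survey_start = survey_start,
    survey_end = submitted_at,
    completeness = completeness,
    ip_address = paste0("10.0.", as.integer(substr(entry_id, 2, 4)) %/% 250,
                        ".", as.integer(substr(entry_id, 2, 4)) %% 250),
    geo_country = "US",
    geo_state = "KY",
    geo_county = "Fayette",
    name_consent = "John Doe",
    name_contact = NA_character_,
    name_incentive = "John Doe",
    email = "john.doe@email.com",
    phone = "8595550100",
    date_of_birth = as.Date("1992-03-04"),
    mail_street = NA_character_,
    mail_city = NA_character_,
    mail_county = NA_character_,
    mail_state = NA_character_,
    mail_country = NA_character_,
    incentive_method = "egift",
    event_participation = FALSE,
    scripted_response = "none"
  )
  overrides <- list(...)
  for (nm in names(overrides)) entry[[nm]] <- overrides[[nm]]
  entry
}

# Several entries an hour apart, ids E001, E002, ...; `...` is a list
# of per-entry override lists.
make_entries <- function(n, overrides = vector("list", n)) {
  purrr::map_dfr(seq_len(n), function(k) {
    ov <- overrides[[k]]
    if (is.null(ov)) ov <- list()
    do.call(make_entry, c(
      list(entry_id = sprintf("E%03d", k),
           submitted = sprintf("2020-01-01 %02d:00:00", 9 + k)),
      ov
    ))
  })
}
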