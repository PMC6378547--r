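area <- test_area()
cfg <- study_config()

test_that("geolocation criterion honors overrides before the location test", {
  # out-of-state estimate, e-gift incentive, no event -> flagged
  e <- make_entry(geo_state = "OH", geo_county = NA_character_)
  r <- eval_geolocation(e, area, cfg)
  expect_equal(r$status, "violated")
  expect_equal(r$points, 1L)
  expect_true(r$raw_out_of_area)

  # out-of-state estimate but payment mailed to an in-area address
  e <- make_entry(geo_state = "NY", geo_county = NA_character_,
                  incentive_method = "mail",
                  mail_street = "1 Elm St", mail_city = "Lexington",
                  mail_county = "Fayette", mail_state = "KY",
                  mail_country = "US")
  r <- eval_geolocation(e, area, cfg)
  expect_equal(r$status, "clear")
  expect_equal(r$points, 0L)
  expect_match(r$evidence, "override:mail")

  # completed at a recruitment event
  e <- make_entry(geo_country = "CA", geo_state = NA_character_,
                  geo_county = NA_character_, event_participation = TRUE)
  r <- eval_geolocation(e, area, cfg)
  expect_equal(r$status, "clear")
  expect_match(r$evidence, "override:event")

  # eligible county is clear; county name matching is case-insensitive
  expect_equal(eval_geolocation(make_entry(geo_county = "FAYETTE"),
                                area, cfg)$status, "clear")
  # in-state estimate with unknown county gets the benefit of the doubt
  expect_equal(eval_geolocation(make_entry(geo_county = NA_character_),
                                area, cfg)$status, "clear")
  # in-state but a county outside the study area is flagged
  expect_equal(eval_geolocation(make_entry(geo_county = "Jefferson"),
                                area, cfg)$status, "violated")
  # no estimate at all cannot be evaluated
  e <- make_entry(geo_country = NA_character_, geo_state = NA_character_,
                  geo_county = NA_character_)
  expect_equal(eval_geolocation(e, area, cfg)$status, "not_evaluable")
})

test_that("phone criterion flags business and invalid lines, skips blanks", {
  dir <- test_directory()
  expect_equal(eval_phone(make_entry(phone = "8595559900"), dir)$status,
               "violated")
  expect_equal(eval_phone(make_entry(phone = "8595550100"), dir)$status,
               "clear")
  # number absent from the offline directory is treated as invalid
  expect_equal(eval_phone(make_entry(phone = "5025550199"), dir)$status,
               "violated")
  r <- eval_phone(make_entry(phone = NA_character_), dir)
  expect_equal(r$status, "not_evaluable")
  expect_equal(r$points, 0L)
})

test_that("names are collected from all sources and normalized", {
  e <- make_entry(name_consent = "JOHN   DOE",
                  name_incentive = NA_character_,
                  email = "john.doe@email.com")
  nm <- extract_names(e)
  expect_equal(nm$name_consent, c("doe", "john"))
  expect_equal(nm$email, c("doe", "john"))
  e <- make_entry(name_consent = NA_character_,
                  name_incentive = NA_character_,
                  email = NA_character_)
  expect_length(extract_names(e), 0L)
})

test_that("within-entry name consistency compares token sets", {
  # two sources with no token in common
  e <- make_entry(name_consent = "John Doe", name_incentive = "Mike Smith",
                  email = NA_character_)
  expect_equal(eval_name_consistency(e, cfg)$status, "violated")
  # a name repeated through the email address is consistent
  e <- make_entry(name_consent = "John Doe",
                  name_incentive = NA_character_,
                  email = "john.doe@email.com")
  expect_equal(eval_name_consistency(e, cfg)$status, "clear")
  # sharing a surname counts as a match, not a mismatch
  e <- make_entry(name_consent = "John Doe", name_incentive = "J. Doe",
                  email = NA_character_)
  expect_equal(eval_name_consistency(e, cfg)$status, "clear")
  # fewer than two usable sources
  e <- make_entry(name_consent = "John Doe",
                  name_incentive = NA_character_, email = NA_character_)
  expect_equal(eval_name_consistency(e, cfg)$status, "not_evaluable")
  # a digits-only email local part contributes no name source
  e <- make_entry(name_consent = "John Doe",
                  name_incentive = NA_character_,
                  email = "19900421@email.com")
  expect_equal(eval_name_consistency(e, cfg)$status, "not_evaluable")
})

test_that("email pattern counts letter/digit run transitions", {
  expect_equal(email_alternations("a12bcd34e@email.com"), 4L)
  expect_equal(email_alternations("john.doe@email.com"), 0L)
  expect_equal(email_alternations("jd1990@email.com"), 1L)

  blank_names <- list(name_consent = NA_character_,
                      name_incentive = NA_character_)
  e <- do.call(make_entry, c(list(email = "a12bcd34e@email.com"),
                             blank_names))
  expect_equal(eval_email_pattern(e, cfg)$status, "violated")
  e <- do.call(make_entry, c(list(email = "jd1990@email.com"),
                             blank_names))
  expect_equal(eval_email_pattern(e, cfg)$status, "clear")
  e <- make_entry(email = "john.doe@email.com")
  expect_equal(eval_email_pattern(e, cfg)$status, "clear")
  # alternating address is excused when a run of >= 3 letters is the
  # respondent's own name
  e <- make_entry(name_consent = "John Doe", email = "john12doe34@email.com")
  expect_equal(eval_email_pattern(e, cfg)$status, "clear")
  e <- make_entry(name_consent = "Mike Smith",
                  name_incentive = "Mike Smith",
                  email = "john12doe34@email.com")
  expect_equal(eval_email_pattern(e, cfg)$status, "violated")
  e <- make_entry(email = NA_character_)
  expect_equal(eval_email_pattern(e, cfg)$status, "not_evaluable")
})

test_that("duration criterion is strict at the five-minute boundary", {
  r <- eval_duration(make_entry(minutes = 4 + 59 / 60), cfg)
  expect_equal(r$status, "violated")
  expect_equal(eval_duration(make_entry(minutes = 5), cfg)$status, "clear")
  expect_equal(eval_duration(make_entry(minutes = 19 + 41 / 60),
                             cfg)$status, "clear")
  e <- make_entry()
  e$survey_start <- as.POSIXct(NA)
  expect_equal(eval_duration(e, cfg)$status, "not_evaluable")
})

test_that("cross-entry rules need a single prior supplying all elements", {
  # phone+email match a previous entry; names and DOB differ
  e <- make_entries(2, overrides = list(
    list(),
    list(name_consent = "Amy Poe", name_incentive = "Amy Poe",
         email = "john.doe@email.com", phone = "8595550100",
         date_of_birth = as.Date("1980-01-01"))
  ))
  res <- eval_cross_entry(e, cfg)
  r2 <- res[res$entry_id == "E002", ]
  expect_equal(r2$status[r2$criterion == "dup_two_items"], "violated")
  expect_equal(r2$points[r2$criterion == "dup_two_items"], 1L)
  expect_equal(r2$status[r2$criterion == "dup_name_plus_item"], "clear")
  expect_equal(r2$status[r2$criterion == "dup_dob_plus_item"], "clear")

  # same name and same email as a previous entry -> 2 points
  e <- make_entries(2, overrides = list(
    list(),
    list(phone = "8595550101", date_of_birth = as.Date("1980-01-01"))
  ))
  res <- eval_cross_entry(e, cfg)
  r2 <- res[res$entry_id == "E002", ]
  expect_equal(r2$status[r2$criterion == "dup_name_plus_item"], "violated")
  expect_equal(r2$points[r2$criterion == "dup_name_plus_item"], 2L)
  expect_equal(r2$status[r2$criterion == "dup_two_items"], "clear")

  # same DOB and same phone -> 2 points via the DOB rule
  e <- make_entries(2, overrides = list(
    list(),
    list(name_consent = "Amy Poe", name_incentive = "Amy Poe",
         email = "amy.poe@email.com")
  ))
  res <- eval_cross_entry(e, cfg)
  r2 <- res[res$entry_id == "E002", ]
  expect_equal(r2$status[r2$criterion == "dup_dob_plus_item"], "violated")
  expect_equal(r2$points[r2$criterion == "dup_dob_plus_item"], 2L)

  # one matching item alone fires nothing
  e <- make_entries(2, overrides = list(
    list(),
    list(name_consent = "Amy Poe", name_incentive = "Amy Poe",
         phone = "8595550101", date_of_birth = as.Date("1980-01-01"))
  ))
  res <- eval_cross_entry(e, cfg)
  r2 <- res[res$entry_id == "E002", ]
  expect_true(all(r2$status == "clear"))

  # name match with one prior and item match with a different prior
  # does not fire: each rule needs one prior supplying everything
  e <- make_entries(3, overrides = list(
    list(),  # E001 shares the name
    list(name_consent = "Amy Poe", name_incentive = "Amy Poe",
         email = "amy.poe@email.com", phone = "8595550101"),  # shares item
    list(email = "amy.poe@email.com", phone = "8595550102",
         date_of_birth = as.Date("1985-05-05"))
  ))
  res <- eval_cross_entry(e, cfg)
  r3 <- res[res$entry_id == "E003", ]
  expect_equal(r3$status[r3$criterion == "dup_name_plus_item"], "clear")

  # missing evidence makes a rule not evaluable
  e <- make_entry(phone = NA_character_, email = NA_character_,
                  name_consent = NA_character_,
                  name_incentive = NA_character_,
                  date_of_birth = as.Date(NA))
  res <- eval_cross_entry(e, cfg)
  expect_true(all(res$status == "not_evaluable"))
})

test_that("scorecards add the points of all eight criteria", {
  dir <- test_directory()
  # geolocation + phone + name mismatch -> 3 points
  e <- make_entry(geo_state = "OH", geo_county = NA_character_,
                  phone = "8595559900", name_consent = "John Doe",
                  name_incentive = "Mike Smith", email = NA_character_)
  card <- score_entry(e, config = cfg, area = area, directory = dir)
  expect_equal(card$total, 3)

  # a clean entry scores zero
  card <- score_entry(make_entry(), config = cfg, area = area,
                      directory = dir)
  expect_equal(card$total, 0)

  # an entry violating every criterion reaches the top of the scale
  prior <- make_entry(entry_id = "E001", submitted = "2020-01-01 09:00:00",
                      name_consent = "Alex Reed",
                      name_incentive = "Alex Reed",
                      email = "a12bcd34e@email.com", phone = "8595559900",
                      date_of_birth = as.Date("1991-07-08"),
                      mail_street = "9 Oak St", mail_city = "Lexington",
                      mail_county = "Fayette")
  worst <- make_entry(entry_id = "E002", submitted = "2020-01-01 12:00:00",
                      minutes = 3,
                      geo_country = "CA", geo_state = NA_character_,
                      geo_county = NA_character_,
                      name_consent = "Alex Reed",
                      name_incentive = "Zed Quill",
                      email = "a12bcd34e@email.com", phone = "8595559900",
                      date_of_birth = as.Date("1991-07-08"),
                      mail_street = "9 Oak St", mail_city = "Lexington",
                      mail_county = "Fayette")
  card <- score_entry(worst, prior, config = cfg, area = area,
                      directory = dir)
  expect_equal(card$total, 10)
  statuses <- unlist(card[paste0(criterion_ids(), "_status")])
  expect_true(all(statuses == "violated"))

  # scoring is pure: identical inputs give identical scorecards
  again <- score_entry(worst, prior, config = cfg, area = area,
                       directory = dir)
  expect_identical(as.data.frame(card), as.data.frame(again))
})
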