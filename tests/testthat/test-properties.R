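# Property-style checks of the scoring engine's invariants, exercised
# on the canonical fixture and on randomized synthetic datasets.

test_that("point totals are bounded by the 0-10 scale on every input", {
  pipe <- get_canonical_pipeline()
  expect_true(all(pipe$scorecards$total >= 0 &
                    pipe$scorecards$total <= 10))
  sim <- generate_synthetic(n = 400, seed = 17)
  cards <- score_entries(sim$entries, directory = sim$phone_directory)
  expect_true(all(cards$total >= 0 & cards$total <= 10))
  # totals equal the sum of the per-criterion points
  pts <- as.matrix(cards[paste0(criterion_ids(), "_points")])
  expect_equal(unname(rowSums(pts)), unname(cards$total))
})

test_that("location overrides never increase a total", {
  fx <- get_canonical()
  kept <- get_canonical_kept()
  base <- get_canonical_pipeline()$scorecards

  flagged <- kept
  flagged$event_participation <- TRUE
  ev <- score_entries(flagged, fx$config,
                      directory = fx$phone_directory)
  expect_true(all(ev$total <= base$total[match(ev$entry_id,
                                               base$entry_id)]))

  mailed <- kept
  mailed$incentive_method <- "mail"
  mailed$mail_street <- paste0(seq_len(nrow(mailed)), " High St")
  mailed$mail_city <- "Lexington"
  mailed$mail_county <- "Fayette"
  mailed$mail_state <- "KY"
  mailed$mail_country <- "US"
  # per-entry unique street keeps the address item from matching
  ml <- score_entries(mailed, fx$config,
                      directory = fx$phone_directory)
  expect_true(all(ml$total <= base$total[match(ml$entry_id,
                                               base$entry_id)]))
})

test_that("blanking optional fields never increases a total", {
  fx <- get_canonical()
  kept <- get_canonical_kept()
  base <- get_canonical_pipeline()$scorecards
  blankable <- c("phone", "email", "date_of_birth", "name_incentive",
                 "name_consent")
  for (field in blankable) {
    blanked <- kept
    blanked[[field]] <- blanked[[field]][NA]
    cards <- score_entries(blanked, fx$config,
                           directory = fx$phone_directory)
    expect_true(
      all(cards$total <= base$total[match(cards$entry_id,
                                          base$entry_id)]),
      label = paste("blanking", field, "never increases totals"))
  }
  # mailing address, for entries not using it for incentive delivery
  nonmail <- kept[kept$incentive_method != "mail", ]
  base_nm <- score_entries(nonmail, fx$config,
                           directory = fx$phone_directory)
  blanked <- nonmail
  for (f in c("mail_street", "mail_city", "mail_county", "mail_state",
              "mail_country")) {
    blanked[[f]] <- NA_character_
  }
  cards <- score_entries(blanked, fx$config,
                         directory = fx$phone_directory)
  expect_true(all(cards$total <= base_nm$total[match(cards$entry_id,
                                                     base_nm$entry_id)]))
})

test_that("duplicate rules never charge the first holder of an item", {
  # three entries: the middle one reuses the first's phone and mailing
  # address (everything else its own)
  shared_addr <- list(mail_street = "7 Pine St", mail_city = "Lexington",
                      mail_county = "Fayette")
  e <- make_entries(3, overrides = list(
    shared_addr,
    c(list(name_consent = "Amy Poe", name_incentive = "Amy Poe",
           email = "amy.poe@email.com",
           date_of_birth = as.Date("1981-02-03")), shared_addr),
    list(name_consent = "Zoe Fox", name_incentive = "Zoe Fox",
         email = "zoe.fox@email.com", phone = "8595550101",
         date_of_birth = as.Date("1982-03-04"))
  ))
  cards <- score_entries(e, directory = test_directory())
  expect_equal(cards$total[cards$entry_id == "E001"], 0)
  expect_equal(cards$total[cards$entry_id == "E002"], 1)
  expect_equal(cards$total[cards$entry_id == "E003"], 0)

  # and at scale: synthetic duplicates only ever charge later copies
  sim <- generate_synthetic(n = 300, seed = 23)
  cards <- score_entries(sim$entries, directory = sim$phone_directory)
  long <- attr(cards, "long")
  dup_rows <- long[long$criterion %in%
                     c("dup_two_items", "dup_name_plus_item",
                       "dup_dob_plus_item") &
                     long$status == "violated", ]
  ord <- match(dup_rows$entry_id, cards$entry_id)
  src <- match(sub("^prior:", "", dup_rows$evidence), cards$entry_id)
  expect_true(all(src < ord))
})

test_that("categorization conserves entries and pays only final-valid", {
  pipe <- get_canonical_pipeline()
  r <- pipe$records
  expect_equal(length(unique(r$entry_id)), nrow(r))
  expect_equal(sum(table(r$initial)), nrow(r))
  expect_equal(sum(table(r$final)), nrow(r))
  moved <- r$final != r$initial
  expect_true(all(r$initial[moved] == "potential_fraud"))
  expect_equal(sum(r$reason == "verified") +
                 sum(r$reason %in% c("admitted_ineligible",
                                     "failed_verification")) +
                 sum(r$initial == "potential_fraud" &
                       r$reason == "no_response"),
               sum(r$initial == "potential_fraud"))
  expect_true(all(r$incentive_payable == (r$final == "valid")))
})

test_that("scoring the same entries twice is idempotent", {
  fx <- get_canonical()
  kept <- get_canonical_kept()
  a <- score_entries(kept, fx$config, directory = fx$phone_directory)
  b <- score_entries(kept, fx$config, directory = fx$phone_directory)
  expect_identical(as.data.frame(a), as.data.frame(b))
})
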