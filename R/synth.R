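# Randomized labeled synthetic-respondent generator for property
# testing, and detector evaluation against ground truth.

synth_archetypes <- function() {
  c("honest_local", "out_of_area", "bot", "duplicate",
    "cohabiting_pair")
}

#' Default archetype prevalences for synthetic data
#'
#' Roughly mirrors the composition observed in the motivating study:
#' about six in ten respondents are honest locals, a quarter are
#' ineligible out-of-area respondents posing as eligible
#' (misrepresentation fraud), a modest share are scripted bots, a few
#' are duplicate submitters, and a few are legitimate cohabiting pairs
#' sharing a phone and address.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_prevalence <- function() {
  c(honest_local = 0.60, out_of_area = 0.25, bot = 0.08,
    duplicate = 0.04, cohabiting_pair = 0.03)
}

#' Generate a labeled synthetic survey dataset
#'
#' Draws `n` entries from five respondent archetypes. Honest locals are
#' clean in-area entries. Out-of-area respondents carry ineligible
#' geolocations and, with configurable probabilities, business phone
#' numbers, internally mismatching names, or bot-style email addresses.
#' Bots get alternating letter/digit emails, short durations and mostly
#' out-of-area geolocations. Duplicates reuse the phone and email of a
#' random earlier entry (sometimes also its name or date of birth).
#' Cohabiting pairs share an address and phone but differ in name and
#' date of birth - the legitimate-sharing case - and verify on
#' recontact. Ground-truth fraud labels mark out-of-area, bot and
#' duplicate entries.
#'
#' @param n Number of entries.
#' @param prevalence Named vector over the five archetypes, summing
#'   to 1.
#' @param seed Integer seed; the same seed gives an identical dataset.
#' @param area A [study_area()].
#' @param criterion_probs Per-archetype probabilities of secondary
#'   violation signals (see defaults in the function signature).
#' @return A list with `entries` (raw entries tibble), `labels`
#'   (`entry_id`, `archetype`, `true_fraud`), and `phone_directory`.
#' @export
generate_synthetic <- function(n,
                               prevalence = default_prevalence(),
                               seed = 1L,
                               area = central_ky_study_area(),
                               criterion_probs = list(
                                 out_of_area = c(business_phone = 0.55,
                                                 name_mismatch = 0.30,
                                                 bot_email = 0.30),
                                 bot = c(out_of_area = 0.80,
                                         business_phone = 0.40,
                                         short_duration = 0.70),
                                 duplicate = c(copy_name = 0.50,
                                               copy_dob = 0.30))) {
  if (!setequal(names(prevalence), synth_archetypes())) {
    abort(paste0("`prevalence` must be named over: ",
                 paste(synth_archetypes(), collapse = ", ")))
  }
  prevalence <- prevalence[synth_archetypes()]
  if (any(prevalence < 0) || abs(sum(prevalence) - 1) > 1e-8) {
    abort("`prevalence` must be non-negative and sum to 1.")
  }
  stopifnot(n >= 0)
  if (n == 0L) {
    empty <- build_canonical_fixture()$entries[0, ]
    return(list(entries = empty,
                labels = tibble(entry_id = character(0),
                                archetype = character(0),
                                true_fraud = logical(0)),
                phone_directory = phone_directory()))
  }
  set.seed(as.integer(seed))
  i <- seq_len(n)
  archetype <- sample(synth_archetypes(), n, replace = TRUE,
                      prob = prevalence)
  # Duplicates and cohabiting partners need a predecessor.
  archetype[1L][archetype[1L] %in%
                  c("duplicate", "cohabiting_pair")] <- "honest_local"

  firstA <- fixture_first_names()[(i - 1L) %% 24L + 1L]
  lastA <- fixture_last_names()[(i - 1L) %% 18L + 1L]
  doms <- c("gmail.com", "yahoo.com", "outlook.com",
            "icloud.com")[(i - 1L) %% 4L + 1L]
  cap <- function(x) paste0(toupper(substr(x, 1, 1)),
                            substr(x, 2, nchar(x)))
  primary <- paste(cap(firstA), cap(lastA))

  name_consent <- primary
  name_incentive <- primary
  email <- paste0(firstA, ".", lastA, i, "@", doms)
  phone <- paste0("859555", sprintf("%05d", i))
  line_type <- rep("personal", n)
  geo_country <- rep("US", n)
  geo_state <- rep("KY", n)
  geo_county <- area$counties[(i - 1L) %% length(area$counties) + 1L]
  mail_street <- rep(NA_character_, n)
  mail_city <- rep(NA_character_, n)
  mail_county <- rep(NA_character_, n)
  mail_state <- rep(NA_character_, n)
  mail_country <- rep(NA_character_, n)
  incentive <- rep("egift", n)
  dob <- as.Date("1988-06-15") + (i * 11L) %% 7000L
  duration <- round(stats::runif(n, 8, 30), 2)
  scripted <- rep("none", n)

  out_state_pool <- c("OH", "TN", "IN", "GA", "FL", "NY", "TX", "IL")
  set_out_of_area <- function(k) {
    cls <- sample(c("nonus", "usnonky", "kyout"), length(k),
                  replace = TRUE, prob = c(0.15, 0.70, 0.15))
    geo_country[k[cls == "nonus"]] <<- "CA"
    geo_state[k[cls == "nonus"]] <<- NA_character_
    geo_county[k[cls == "nonus"]] <<- NA_character_
    geo_state[k[cls == "usnonky"]] <<-
      sample(out_state_pool, sum(cls == "usnonky"), replace = TRUE)
    geo_county[k[cls == "usnonky"]] <<- NA_character_
    geo_county[k[cls == "kyout"]] <<- "Jefferson"
  }

  ooa <- which(archetype == "out_of_area")
  if (length(ooa)) {
    set_out_of_area(ooa)
    p <- criterion_probs$out_of_area
    biz <- ooa[stats::runif(length(ooa)) < p[["business_phone"]]]
    phone[biz] <- paste0("859771", sprintf("%05d", biz))
    line_type[biz] <- "business_or_org"
    mis <- ooa[stats::runif(length(ooa)) < p[["name_mismatch"]]]
    alt <- paste(cap(fixture_alt_first_names()[(mis - 1L) %% 12L + 1L]),
                 cap(fixture_alt_last_names()[(mis - 1L) %% 12L + 1L]))
    name_incentive[mis] <- alt
    bot_email <- ooa[stats::runif(length(ooa)) < p[["bot_email"]]]
    email[bot_email] <- paste0(bot_email, "x", (bot_email * 3L) %% 10L,
                               "q", (bot_email * 7L) %% 10L, "w@",
                               doms[bot_email])
  }

  bots <- which(archetype == "bot")
  if (length(bots)) {
    p <- criterion_probs$bot
    email[bots] <- paste0(bots, "x", (bots * 3L) %% 10L, "q",
                          (bots * 7L) %% 10L, "w@", doms[bots])
    name_incentive[bots] <- NA_character_
    out <- bots[stats::runif(length(bots)) < p[["out_of_area"]]]
    if (length(out)) set_out_of_area(out)
    biz <- bots[stats::runif(length(bots)) < p[["business_phone"]]]
    phone[biz] <- paste0("859771", sprintf("%05d", biz))
    line_type[biz] <- "business_or_org"
    short <- bots[stats::runif(length(bots)) < p[["short_duration"]]]
    duration[short] <- round(stats::runif(length(short), 1.5, 4.5), 2)
  }

  dups <- which(archetype == "duplicate")
  p_dup <- criterion_probs$duplicate
  for (k in dups) {
    srcpool <- which(seq_len(n) < k & archetype != "duplicate")
    if (length(srcpool) == 0L) srcpool <- seq_len(k - 1L)
    s <- srcpool[sample.int(length(srcpool), 1L)]
    phone[k] <- phone[s]
    line_type[k] <- line_type[s]
    email[k] <- email[s]
    if (stats::runif(1) < p_dup[["copy_name"]]) {
      name_consent[k] <- name_consent[s]
      name_incentive[k] <- name_consent[s]
    }
    if (stats::runif(1) < p_dup[["copy_dob"]]) dob[k] <- dob[s]
  }

  cohab <- which(archetype == "cohabiting_pair")
  if (length(cohab) >= 2L) {
    pairs <- matrix(cohab[seq_len(2L * (length(cohab) %/% 2L))],
                    ncol = 2L, byrow = TRUE)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1L]; b <- pairs[r, 2L]
      street <- paste0(a, " Rose St")
      county <- geo_county[a]
      for (k in c(a, b)) {
        mail_street[k] <- street
        mail_city[k] <- "Lexington"
        mail_county[k] <- county
        mail_state[k] <- "KY"
        mail_country[k] <- "US"
        incentive[k] <- "mail"
      }
      phone[b] <- phone[a]
      # Names and dates of birth must differ (legitimate sharing, not
      # duplicate fraud); the second of the pair verifies on recontact.
      if (identical(name_consent[b], name_consent[a])) {
        alt <- paste(cap(fixture_alt_first_names()[(b - 1L) %% 12L + 1L]),
                     cap(fixture_alt_last_names()[(b - 1L) %% 12L + 1L]))
        name_consent[b] <- alt
        name_incentive[b] <- alt
      }
      if (!is.na(dob[a]) && !is.na(dob[b]) && dob[a] == dob[b]) {
        dob[b] <- dob[b] + 1L
      }
      scripted[b] <- "verified"
    }
  }

  t0 <- as.POSIXct("2021-03-01 09:00:00", tz = "UTC")
  survey_end <- t0 + i * 1800
  survey_start <- survey_end - duration * 60
  entries <- tibble(
    entry_id = sprintf("Y%05d", i),
    submitted_at = survey_end,
    screening_start = survey_start - 420,
    screening_end = survey_start - 180,
    consent_start = survey_start - 180,
    consent_end = survey_start,
    survey_start = survey_start,
    survey_end = survey_end,
    completeness = 1,
    ip_address = paste0("73.20.", i %/% 250L, ".", i %% 250L),
    geo_country = geo_country,
    geo_state = geo_state,
    geo_county = geo_county,
    name_consent = name_consent,
    name_contact = NA_character_,
    name_incentive = name_incentive,
    email = email,
    phone = phone,
    date_of_birth = dob,
    mail_street = mail_street,
    mail_city = mail_city,
    mail_county = mail_county,
    mail_state = mail_state,
    mail_country = mail_country,
    incentive_method = incentive,
    event_participation = FALSE,
    scripted_response = scripted
  )
  labels <- tibble(
    entry_id = entries$entry_id,
    archetype = archetype,
    true_fraud = archetype %in% c("out_of_area", "bot", "duplicate")
  )
  keep <- !duplicated(normalize_phone(phone)) & !is.na(phone)
  directory <- phone_directory(phone[keep], line_type[keep])
  list(entries = entries, labels = labels,
       phone_directory = directory)
}

#' Evaluate detector output against ground-truth labels
#'
#' Treats a final category of fraud as the positive call and the
#' `true_fraud` label as the condition. Sensitivity and specificity are
#' `NA` when their denominator is zero.
#'
#' @param records Category-records tibble (from [run_pipeline()] or
#'   [resolve_recontact()]).
#' @param labels Labels tibble with `entry_id` and `true_fraud`.
#' @return One-row tibble `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`; the 2x2 table is attached as attribute
#'   `"confusion"`.
#' @export
evaluate_detector <- function(records, labels) {
  if (!setequal(records$entry_id, labels$entry_id)) {
    abort("`records` and `labels` must cover the same entry ids.")
  }
  joined <- left_join(records, labels, by = "entry_id")
  pred <- joined$final == "fraud"
  truth <- joined$true_fraud
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  tn <- sum(!pred & !truth)
  rate <- function(num, den) if (den == 0L) NA_real_ else num / den
  out <- tibble(tp = tp, fp = fp, fn = fn, tn = tn,
                sensitivity = rate(tp, tp + fn),
                specificity = rate(tn, tn + fp))
  attr(out, "confusion") <- matrix(
    c(tp, fn, fp, tn), nrow = 2L,
    dimnames = list(predicted = c("fraud", "not_fraud"),
                    truth = c("fraud", "not_fraud")))
  out
}
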