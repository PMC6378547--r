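# Deterministic canonical fixture: 434 raw survey records whose
# violation patterns, overrides, IP sharing and recontact outcomes
# realize the published study's marginals and cross-tabulations. The
# construction is seedless and bit-stable: field values follow fixed
# index-based recipes so that each entry violates exactly its block's
# criteria and no others.

fixture_first_names <- function() {
  c("james", "liam", "noah", "ethan", "mason", "logan", "lucas",
    "henry", "jack", "owen", "levi", "ryan", "caleb", "dylan", "isaac",
    "nathan", "aaron", "adam", "blake", "cole", "evan", "gavin", "ian",
    "jason")
}

fixture_last_names <- function() {
  c("carter", "brooks", "hayes", "porter", "reed", "coleman", "barnes",
    "fisher", "graham", "holland", "kemp", "lawson", "mills", "norris",
    "owens", "parks", "quinn", "ross")
}

# Disjoint pools used for the mismatching second name within an entry.
fixture_alt_first_names <- function() {
  c("victor", "warren", "xavier", "yusuf", "zane", "marcus", "felix",
    "oscar", "hugo", "silas", "rufus", "amos")
}

fixture_alt_last_names <- function() {
  c("thompson", "underwood", "vance", "walker", "yates", "zimmerman",
    "sutton", "tate", "ulrich", "vaughn", "watts", "yoder")
}

# Ordered pattern blocks. Row order is submission order; block counts
# and criterion patterns encode the study's Table-1 and flow-count
# structure (criteria: A geolocation, B phone, C name mismatch, D email
# pattern, E name+item, F2 two items, G dob+item, H duration).
fixture_plan <- function() {
  blk <- function(block, n, ...) {
    args <- utils::modifyList(
      list(names = "pair", email = "name", phone = "personal",
           geo = "in", dob = "unique", event = FALSE,
           incentive = "egift", scripted = "none", completeness = 1,
           duration = NA_real_, ip = NA_character_,
           dup_source = NA_integer_),
      list(...))
    do.call(tibble, c(list(block = block, .rows = n), args))
  }
  plan <- bind_rows(
    # --- final valid: 143 clean -------------------------------------
    blk("clean_sparse", 67, phone = "blank", email = "none"),
    blk("clean_anon", 16, names = "none", email = "alias",
        phone = "blank"),
    blk("clean_basic", 10, phone = "blank"),
    blk("clean_source", 16,
        email = c(rep("plain", 6), rep("name", 10))),
    blk("clean_full", 34, completeness = c(rep(1, 28), rep(0.72, 6))),
    # --- final valid: 82 out-of-area geolocations, overridden -------
    blk("override_event", 13, geo = "out", event = TRUE,
        incentive = "in_person", ip = "venue"),
    blk("override_mail", 69, geo = "out", incentive = "mail"),
    # --- final valid: 28 single-violation entries, verified ---------
    blk("verified_a", 21, geo = "out", scripted = "verified"),
    blk("verified_c", 4, names = "mismatch", email = "plain",
        scripted = "verified"),
    blk("verified_d", 2, names = "single", email = "bot",
        scripted = "verified"),
    blk("verified_h", 1, duration = 3, scripted = "verified"),
    # --- final potential fraud (no response): 42 --------------------
    blk("potential_a_sparse", 20, geo = "out", names = "single",
        email = "plain"),
    blk("potential_a_full", 14, geo = "out"),
    blk("potential_c", 2, names = "mismatch", email = "none"),
    blk("potential_d", 1, names = "single", email = "bot"),
    blk("potential_f2", 3, phone = "dup", email = "dup",
        dup_source = 94:96),
    blk("potential_h", 2, duration = c(4, 4.5)),
    # --- final fraud: 119 -------------------------------------------
    blk("fraud_a_admitted", 2, geo = "out",
        scripted = "admitted_ineligible"),
    blk("fraud_ab", 37, geo = "out", phone = "business"),
    blk("fraud_abc", 29, geo = "out", phone = "business",
        names = "mismatch", email = "none"),
    blk("fraud_abd", 28, geo = "out", phone = "business",
        names = "single", email = "bot"),
    blk("fraud_ac", 4, geo = "out", names = "mismatch",
        email = "plain"),
    blk("fraud_ad", 4, geo = "out", names = "single", email = "bot"),
    blk("fraud_acd", 2, geo = "out", names = "mismatch",
        email = "bot"),
    blk("fraud_ae", 3, geo = "out", names = "dup_pair", email = "dup",
        dup_source = 100:102),
    blk("fraud_ce", 2, names = "dup_mismatch", email = "dup",
        dup_source = 103:104),
    blk("fraud_eg", 5, names = "dup_pair", email = "dup", dob = "dup",
        dup_source = 105:109),
    blk("fraud_ef2", 3, names = "dup_pair", email = "dup",
        phone = "dup", dup_source = 97:99),
    # --- partial records dropped by the completeness filter ---------
    blk("partial_low", 18, completeness = 0.30),
    blk("partial_mid", 2, completeness = 0.45)
  )
  # Five early clean entries gave no date of birth.
  plan$dob[1:5] <- "missing"
  plan
}

fixture_final_category <- function(block) {
  dplyr::case_when(
    grepl("^fraud_", block) ~ "fraud",
    grepl("^potential_", block) ~ "potential_fraud",
    grepl("^partial_", block) ~ "dropped",
    TRUE ~ "valid"
  )
}

#' Build the canonical fixture dataset
#'
#' Deterministically constructs 434 raw survey records (408 complete,
#' 6 partials at or above the 50% completeness floor, 20 below it)
#' together with a matching offline phone directory and study
#' configuration. After the completeness filter the 414 evaluable
#' entries reproduce, through the scoring and categorization pipeline,
#' the published per-criterion counts by final category, the
#' initial/final flow counts, the geolocation override and breakdown
#' figures, and the IP-address-sharing cross-tabulation. Construction
#' is seedless: two builds are identical.
#'
#' @param dir Optional directory; when given, `entries.csv`,
#'   `phone_directory.csv`, `study_config.json` and `manifest.json` are
#'   written there.
#' @return A list with elements `entries` (tibble of 434 raw records),
#'   `phone_directory`, `config` ([study_config()]), and `manifest`
#'   (per-entry block/role table with a block-composition summary in
#'   attribute `"blocks"`).
#' @export
build_canonical_fixture <- function(dir = NULL) {
  plan <- fixture_plan()
  n <- nrow(plan)
  i <- seq_len(n)
  area <- central_ky_study_area()
  config <- study_config(study_area = area)

  cap <- function(x) {
    ifelse(is.na(x), x,
           paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x))))
  }
  firstA <- fixture_first_names()[(i - 1L) %% 24L + 1L]
  lastA <- fixture_last_names()[(i - 1L) %% 18L + 1L]
  firstB <- fixture_alt_first_names()[(i - 1L) %% 12L + 1L]
  lastB <- fixture_alt_last_names()[(i - 1L) %% 12L + 1L]
  primary <- paste(cap(firstA), cap(lastA))
  alternate <- paste(cap(firstB), cap(lastB))

  name_consent <- rep(NA_character_, n)
  name_incentive <- rep(NA_character_, n)
  name_consent[plan$names %in% c("pair", "single", "mismatch")] <-
    primary[plan$names %in% c("pair", "single", "mismatch")]
  name_incentive[plan$names == "pair"] <- primary[plan$names == "pair"]
  name_incentive[plan$names == "mismatch"] <-
    alternate[plan$names == "mismatch"]
  src <- plan$dup_source
  dup_pair <- plan$names == "dup_pair"
  name_consent[dup_pair] <- primary[src[dup_pair]]
  name_incentive[dup_pair] <- primary[src[dup_pair]]
  dup_mis <- plan$names == "dup_mismatch"
  name_consent[dup_mis] <- primary[src[dup_mis]]
  name_incentive[dup_mis] <- alternate[dup_mis]

  doms <- c("gmail.com", "yahoo.com", "outlook.com",
            "icloud.com")[(i - 1L) %% 4L + 1L]
  email <- rep(NA_character_, n)
  email[plan$email == "name"] <-
    paste0(firstA, ".", lastA, i, "@", doms)[plan$email == "name"]
  email[plan$email == "plain"] <-
    paste0("m", 100L + i, "@", doms)[plan$email == "plain"]
  email[plan$email == "alias"] <-
    paste0("qz", 100L + i, "@", doms)[plan$email == "alias"]
  email[plan$email == "bot"] <-
    paste0(i, "x", (i * 3L) %% 10L, "q", (i * 7L) %% 10L, "w@",
           doms)[plan$email == "bot"]
  email[plan$email == "dup"] <- email[src[plan$email == "dup"]]

  phone <- rep(NA_character_, n)
  phone[plan$phone == "personal"] <-
    paste0("859555", sprintf("%04d", i))[plan$phone == "personal"]
  phone[plan$phone == "business"] <-
    paste0("859771", sprintf("%04d", i))[plan$phone == "business"]
  phone[plan$phone == "dup"] <- phone[src[plan$phone == "dup"]]

  # Geolocation classes for the 164 unoverridden violators, assigned
  # in block order: 23 outside the US, 118 in other US states, 23 in
  # the state but outside the study area. Overridden entries carry an
  # other-state estimate.
  is_override <- plan$block %in% c("override_event", "override_mail")
  violator <- plan$geo == "out" & !is_override
  geo_class <- rep("in", n)
  geo_class[is_override] <- "usnonky"
  rank <- cumsum(violator)
  geo_class[violator & rank <= 23L] <- "nonus"
  geo_class[violator & rank > 23L & rank <= 141L] <- "usnonky"
  geo_class[violator & rank > 141L] <- "kyout"

  eligible <- area$counties[(i - 1L) %% 15L + 1L]
  geo_country <- rep("US", n)
  geo_state <- rep("KY", n)
  geo_county <- eligible
  nonus_pool <- c("CA", "GB", "NG", "IN", "PH")[(i - 1L) %% 5L + 1L]
  us_pool <- c("OH", "TN", "IN", "GA", "FL", "NY", "TX",
               "IL")[(i - 1L) %% 8L + 1L]
  kyout_pool <- c("Jefferson", "Kenton", "Warren", "Daviess", "Pike",
                  "Laurel", "Boyd", "Campbell")[(i - 1L) %% 8L + 1L]
  sel <- geo_class == "nonus"
  geo_country[sel] <- nonus_pool[sel]
  geo_state[sel] <- NA_character_
  geo_county[sel] <- NA_character_
  sel <- geo_class == "usnonky"
  geo_state[sel] <- us_pool[sel]
  geo_county[sel] <- NA_character_
  sel <- geo_class == "kyout"
  geo_county[sel] <- kyout_pool[sel]

  mail <- plan$incentive == "mail"
  mail_street <- ifelse(mail, paste0(i, " Walnut St"), NA_character_)
  mail_city <- ifelse(mail, "Lexington", NA_character_)
  mail_county <- ifelse(mail, eligible, NA_character_)
  mail_state <- ifelse(mail, "KY", NA_character_)
  mail_country <- ifelse(mail, "US", NA_character_)

  dob <- as.Date("1990-01-01") + (i * 7L) %% 6000L
  dob[plan$dob == "missing"] <- NA
  dob[plan$dob == "dup"] <- dob[src[plan$dob == "dup"]]

  duration <- ifelse(is.na(plan$duration), 14 + (i %% 13L),
                     plan$duration)
  t0 <- as.POSIXct("2018-02-15 08:00:00", tz = "UTC")
  survey_end <- t0 + i * 3600
  survey_start <- survey_end - duration * 60
  consent_end <- survey_start
  consent_start <- consent_end - 180
  screening_end <- consent_start
  screening_start <- screening_end - 240

  # IP sharing: one 13-entry venue address, 41 two-entry pairs
  # (fraud-valid, potential-valid, valid-valid), all other addresses
  # unique.
  ip <- paste0("73.148.", i %/% 250L, ".", i %% 250L)
  ip[plan$ip %in% "venue"] <- "74.128.50.10"
  pair_a <- c(298:320, 274:285, 85, 87, 89, 91, 93, 82)
  pair_b <- c(110:132, c(133:143, 84), 86, 88, 90, 92, 81, 83)
  pair_id <- c(1:23, 24:35, 36:41)
  ip[pair_a] <- paste0("74.128.61.", pair_id)
  ip[pair_b] <- paste0("74.128.61.", pair_id)

  entries <- tibble(
    entry_id = sprintf("S%04d", i),
    submitted_at = survey_end,
    screening_start = screening_start,
    screening_end = screening_end,
    consent_start = consent_start,
    consent_end = consent_end,
    survey_start = survey_start,
    survey_end = survey_end,
    completeness = plan$completeness,
    ip_address = ip,
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
    incentive_method = plan$incentive,
    event_participation = plan$event,
    scripted_response = plan$scripted
  )

  business <- plan$phone == "business"
  directory <- phone_directory(
    phone = phone[!is.na(phone)],
    line_type = ifelse(business, "business_or_org",
                       "personal")[!is.na(phone)]
  )

  manifest <- tibble(
    entry_id = entries$entry_id,
    block = plan$block,
    final_expected = fixture_final_category(plan$block),
    geo_class = geo_class,
    overridden = is_override,
    dup_source_id = ifelse(is.na(src), NA_character_,
                           sprintf("S%04d", src)),
    ip_shared = ip %in% ip[duplicated(ip)]
  )
  attr(manifest, "blocks") <- dplyr::count(plan, .data$block)

  stopifnot(nrow(entries) == 434L,
            sum(entries$completeness >= config$completeness_min) == 414L,
            sum(violator) == 164L,
            sum(is_override) == 82L)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_entries(entries, file.path(dir, "entries.csv"))
    write_phone_directory(directory,
                          file.path(dir, "phone_directory.csv"))
    write_study_config(config, file.path(dir, "study_config.json"))
    blocks <- attr(manifest, "blocks")
    jsonlite::write_json(
      list(n_raw = nrow(entries),
           n_evaluable = sum(entries$completeness >=
                               config$completeness_min),
           blocks = blocks),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }

  list(entries = entries, phone_directory = directory, config = config,
       manifest = manifest)
}
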