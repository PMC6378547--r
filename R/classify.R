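# Categorization, recontact messaging, and the verification state
# machine that resolves final categories.

category_levels <- function() c("valid", "potential_fraud", "fraud")

#' Categorize point totals
#'
#' Under the default thresholds an entry is `fraud` at 2 or more total
#' points, `potential_fraud` at exactly 1, and `valid` at 0. Categories
#' are monotone non-decreasing in the total.
#'
#' @param total Numeric vector of scorecard totals.
#' @param config A [study_config()].
#' @return Character vector of categories.
#' @export
categorize <- function(total, config = study_config()) {
  if (any(total < 0, na.rm = TRUE)) abort("Totals must be non-negative.")
  dplyr::case_when(
    total >= config$fraud_threshold ~ "fraud",
    total >= config$potential_threshold ~ "potential_fraud",
    TRUE ~ "valid"
  )
}

#' Compose the recontact message for a flagged entry
#'
#' Returns the category's message template (stored as an editable text
#' file under `inst/templates/`) with the callback number and study name
#' filled in, together with the contact channel chosen in priority
#' order: phone (SMS), then email, then none. Valid entries get no
#' message: asking for one is an error.
#'
#' @param category `"fraud"` or `"potential_fraud"`.
#' @param entry One-row entries tibble.
#' @param callback_number Phone number inserted into the template.
#' @param study_name Study name inserted into the template.
#' @param channel_priority Contact channels in preference order.
#' @return A list with elements `text` and `channel`.
#' @export
compose_message <- function(category, entry,
                            callback_number = "xxx-xxx-xxxx",
                            study_name = "the health study",
                            channel_priority = c("phone", "email")) {
  if (!category %in% c("fraud", "potential_fraud")) {
    abort("No recontact message is defined for valid entries.")
  }
  file <- system.file("templates",
                      if (category == "fraud") "fraud.txt"
                      else "potential.txt",
                      package = "surveyfraud")
  text <- paste(readLines(file, warn = FALSE), collapse = "\n")
  text <- gsub("{callback_number}", callback_number, text, fixed = TRUE)
  text <- gsub("{study_name}", study_name, text, fixed = TRUE)
  channel <- "none"
  for (ch in channel_priority) {
    value <- if (ch == "phone") entry$phone[[1]] else entry$email[[1]]
    if (!is.na(value) && trimws(value) != "") {
      channel <- if (ch == "phone") "sms" else "email"
      break
    }
  }
  list(text = text, channel = channel)
}

#' Resolve categories through the recontact state machine
#'
#' Applies each entry's recontact outcome to its initial category.
#' Potential-fraud entries are the only ones that can move: a verified
#' response reclassifies them as valid; an admission of ineligibility or
#' a failed verification reclassifies them as fraud; silence leaves them
#' potentially fraudulent. Fraud and valid are absorbing. A verified
#' response on a fraud-categorized entry has no defined transition: the
#' record is flagged for manual review (`needs_review`) with a warning
#' and left unchanged. Incentives are payable exactly for final-valid
#' entries.
#'
#' @param records Tibble with columns `entry_id` and `initial` (and
#'   optionally `final` equal to `initial`).
#' @param response Character vector of recontact outcomes (`none`,
#'   `verified`, `admitted_ineligible`, `failed_verification`), recycled
#'   if length 1.
#' @return A category-records tibble: `entry_id`, `initial`, `final`,
#'   `reason`, `incentive_payable`, `needs_review`.
#' @export
resolve_recontact <- function(records, response = "none") {
  stopifnot(all(c("entry_id", "initial") %in% names(records)))
  if (!all(records$initial %in% category_levels())) {
    abort("Unknown initial category.")
  }
  if ("final" %in% names(records) &&
      any(records$final != records$initial)) {
    abort("`records` must be unresolved (final equal to initial).")
  }
  n <- nrow(records)
  response <- rep_len(response, n)
  bad <- setdiff(unique(response), scripted_levels())
  if (length(bad)) {
    abort(paste0("Unknown recontact response: ",
                 paste(bad, collapse = ", ")))
  }
  final <- records$initial
  reason <- rep("none", n)
  needs_review <- rep(FALSE, n)

  pot <- records$initial == "potential_fraud"
  final[pot & response == "verified"] <- "valid"
  reason[pot & response == "verified"] <- "verified"
  final[pot & response == "admitted_ineligible"] <- "fraud"
  reason[pot & response == "admitted_ineligible"] <- "admitted_ineligible"
  final[pot & response == "failed_verification"] <- "fraud"
  reason[pot & response == "failed_verification"] <- "failed_verification"
  reason[pot & response == "none"] <- "no_response"
  reason[records$initial == "fraud" & response == "none"] <- "no_response"

  odd <- records$initial == "fraud" & response == "verified"
  if (any(odd)) {
    warn(paste0(sum(odd), " fraud-categorized entr",
                if (sum(odd) == 1L) "y" else "ies",
                " reported a verified response; flagged for manual",
                " review, category unchanged."))
    needs_review[odd] <- TRUE
  }

  tibble(entry_id = records$entry_id,
         initial = records$initial,
         final = final,
         reason = reason,
         incentive_payable = final == "valid",
         needs_review = needs_review)
}

#' Run the full fraud-detection pipeline
#'
#' Scores each (already completeness-filtered) entry against all
#' chronologically prior entries, assigns initial categories from the
#' point totals, and resolves final categories by applying each entry's
#' recontact outcome (`scripted_response`). Deterministic: a pure
#' function of its inputs.
#'
#' @inheritParams score_entries
#' @return A `fraud_pipeline` object: a list with elements `scorecards`,
#'   `records`, `entries` and `config`. [tidy()] gives one row per
#'   entry; [glance()] a one-row summary.
#' @export
run_pipeline <- function(entries, config = study_config(),
                         area = config$study_area,
                         directory = phone_directory()) {
  entries <- entries |> arrange(.data$submitted_at, .data$entry_id)
  scorecards <- score_entries(entries, config, area, directory)
  records <- tibble(entry_id = scorecards$entry_id,
                    initial = categorize(scorecards$total, config))
  records <- resolve_recontact(records, entries$scripted_response)
  structure(list(scorecards = scorecards, records = records,
                 entries = entries, config = config),
            class = "fraud_pipeline")
}

#' @export
print.fraud_pipeline <- function(x, ...) {
  g <- glance(x)
  cat("<fraud_pipeline> ", g$n_entries, " entries\n", sep = "")
  cat("  initial: fraud ", g$initial_fraud, ", potential ",
      g$initial_potential_fraud, ", valid ", g$initial_valid, "\n",
      sep = "")
  cat("  final:   fraud ", g$final_fraud, ", potential ",
      g$final_potential_fraud, ", valid ", g$final_valid, "\n", sep = "")
  invisible(x)
}

#' Tidy a fraud pipeline into one row per entry
#'
#' @param x A `fraud_pipeline`.
#' @param ... Unused.
#' @return Tibble joining each entry's point total, per-criterion
#'   statuses, and initial/final categories.
#' @method tidy fraud_pipeline
#' @export
tidy.fraud_pipeline <- function(x, ...) {
  cards <- as_tibble(x$scorecards)
  attr(cards, "long") <- NULL
  attr(cards, "raw_out_of_area") <- NULL
  left_join(cards, x$records, by = "entry_id")
}

#' One-row summary of a fraud pipeline
#'
#' @param x A `fraud_pipeline`.
#' @param ... Unused.
#' @return One-row tibble of entry counts by stage and category.
#' @method glance fraud_pipeline
#' @export
glance.fraud_pipeline <- function(x, ...) {
  cnt <- function(v, lev) sum(v == lev)
  r <- x$records
  tibble(n_entries = nrow(r),
         initial_fraud = cnt(r$initial, "fraud"),
         initial_potential_fraud = cnt(r$initial, "potential_fraud"),
         initial_valid = cnt(r$initial, "valid"),
         reclassified_valid = sum(r$reason == "verified"),
         reclassified_fraud = sum(r$reason %in%
                                    c("admitted_ineligible",
                                      "failed_verification")),
         final_fraud = cnt(r$final, "fraud"),
         final_potential_fraud = cnt(r$final, "potential_fraud"),
         final_valid = cnt(r$final, "valid"))
}

#' Write category records to CSV
#'
#' @param records Category-records tibble from [resolve_recontact()] or
#'   a pipeline's `records` element.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_category_records <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
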