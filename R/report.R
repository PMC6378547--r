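# Descriptive reports: criterion table, categorization flow,
# IP-address sharing, geolocation breakdown.

# Round-half-up at `digits` decimals (table-style percentage
# formatting; base round() is round-half-even).
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

pct <- function(num, den, digits = 1L) {
  if (den == 0L) return(0)
  round_half_up(100 * num / den, digits)
}

check_aligned <- function(a, b, what) {
  if (!setequal(a, b)) {
    abort(paste0("Misaligned entry ids between ", what, "."))
  }
}

#' Per-criterion violation table by final category
#'
#' For each of the eight criteria: the number and percentage of
#' evaluable entries violating it, the number recorded as missing (not
#' evaluable), and the violation count and percentage within each final
#' category. Percentages use the evaluable total as denominator for the
#' overall and missing columns and the category size within categories;
#' they are rounded half-up to one decimal.
#'
#' @param entries Evaluable entries tibble.
#' @param scorecards Result of [score_entries()].
#' @param records Category records (final categories).
#' @return A `criterion_table` tibble, one row per criterion.
#' @export
criterion_table <- function(entries, scorecards, records) {
  check_aligned(entries$entry_id, scorecards$entry_id,
                "entries and scorecards")
  check_aligned(entries$entry_id, records$entry_id,
                "entries and records")
  n_total <- nrow(entries)
  cards <- left_join(as_tibble(scorecards),
                     records[c("entry_id", "final")], by = "entry_id")
  rows <- purrr::map_dfr(criterion_ids(), function(cr) {
    st <- cards[[paste0(cr, "_status")]]
    viol <- st == "violated"
    by_cat <- function(cat) {
      n_cat <- sum(cards$final == cat)
      n_v <- sum(viol & cards$final == cat)
      tibble("{cat}_n" := n_v, "{cat}_pct" := pct(n_v, n_cat))
    }
    dplyr::bind_cols(
      tibble(criterion = cr,
             n_violated = sum(viol),
             pct_violated = pct(sum(viol), n_total),
             n_missing = sum(st == "not_evaluable"),
             pct_missing = pct(sum(st == "not_evaluable"), n_total)),
      by_cat("fraud"), by_cat("potential_fraud"), by_cat("valid"))
  })
  class(rows) <- c("criterion_table", class(rows))
  rows
}

#' Categorization flow summary
#'
#' The entry funnel and categorization flow: raw records, exclusions
#' below the completeness floor, evaluable entries, initial categories,
#' recontact resolutions, and final categories.
#'
#' @param records Category records from the pipeline.
#' @param filter_report Either the tibble returned by
#'   [filter_completeness()] (whose attributes carry the raw and
#'   dropped counts) or a list with `n_input` and `n_dropped`;
#'   optional.
#' @return A `flow_summary` tibble with columns `stage` and `n`.
#' @export
flow_summary <- function(records, filter_report = NULL) {
  n_raw <- NA_integer_
  n_dropped <- NA_integer_
  if (!is.null(filter_report)) {
    if (is.data.frame(filter_report)) {
      n_raw <- attr(filter_report, "n_input") %||% NA_integer_
      n_dropped <- attr(filter_report, "n_dropped") %||% NA_integer_
    } else {
      n_raw <- filter_report$n_input %||% NA_integer_
      n_dropped <- filter_report$n_dropped %||% NA_integer_
    }
  }
  cnt <- function(v, lev) sum(v == lev)
  out <- tibble(
    stage = c("raw_records", "excluded_incomplete", "evaluable",
              "initial_fraud", "initial_potential_fraud",
              "initial_valid", "resolved_verified",
              "resolved_admitted_ineligible",
              "resolved_failed_verification", "resolved_no_response",
              "final_fraud", "final_potential_fraud", "final_valid"),
    n = c(n_raw, n_dropped, nrow(records),
          cnt(records$initial, "fraud"),
          cnt(records$initial, "potential_fraud"),
          cnt(records$initial, "valid"),
          sum(records$reason == "verified"),
          sum(records$reason == "admitted_ineligible"),
          sum(records$reason == "failed_verification"),
          sum(records$initial == "potential_fraud" &
                records$reason == "no_response"),
          cnt(records$final, "fraud"),
          cnt(records$final, "potential_fraud"),
          cnt(records$final, "valid"))
  )
  class(out) <- c("flow_summary", class(out))
  out
}

#' IP-address sharing report
#'
#' An entry is "shared" when at least one other evaluable entry carries
#' the identical IP address. Entries completed at recruitment events
#' are reported separately; the remainder is broken down by final
#' category. Informational only: IP sharing never contributes points.
#'
#' @param entries Evaluable entries tibble.
#' @param records Category records.
#' @return One-row tibble: `shared_total`, `event_shared`, and
#'   non-event shared counts by final category.
#' @export
ip_share_report <- function(entries, records) {
  check_aligned(entries$entry_id, records$entry_id,
                "entries and records")
  ip <- entries$ip_address
  shared <- !is.na(ip) & ip %in% ip[duplicated(ip)]
  final <- records$final[match(entries$entry_id, records$entry_id)]
  ev <- entries$event_participation
  tibble(
    shared_total = sum(shared),
    event_shared = sum(shared & ev),
    nonevent_valid = sum(shared & !ev & final == "valid"),
    nonevent_potential_fraud = sum(shared & !ev &
                                     final == "potential_fraud"),
    nonevent_fraud = sum(shared & !ev & final == "fraud")
  )
}

#' Breakdown of unoverridden geolocation violations
#'
#' Partitions the entries that received the geolocation point into
#' three disjoint classes: outside the country, inside the country but
#' in another state, and in the study state but outside the eligible
#' counties. Counts sum to the criterion total.
#'
#' @param entries Evaluable entries tibble.
#' @param scorecards Result of [score_entries()].
#' @param area A [study_area()].
#' @return Tibble with columns `class` and `n` (three rows).
#' @export
geolocation_breakdown <- function(entries, scorecards,
                                  area = central_ky_study_area()) {
  check_aligned(entries$entry_id, scorecards$entry_id,
                "entries and scorecards")
  st <- scorecards$geolocation_status[match(entries$entry_id,
                                            scorecards$entry_id)]
  viol <- st == "violated"
  non_country <- viol & (is.na(entries$geo_country) |
                           entries$geo_country != area$country)
  other_state <- viol & !non_country &
    (is.na(entries$geo_state) | entries$geo_state != area$state)
  in_state <- viol & !non_country & !other_state
  tibble(
    class = c("non_us", "us_non_study_state", "in_state_outside_area"),
    n = c(sum(non_country), sum(other_state), sum(in_state))
  )
}

#' Render a report as JSON
#'
#' @param x Any report tibble or list from this package.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(as.data.frame(x), dataframe = "rows",
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Render a report as an aligned text table
#'
#' @param x A report tibble.
#' @return Character vector of lines.
#' @export
report_text <- function(x) {
  df <- as.data.frame(x)
  utils::capture.output(print(df, row.names = FALSE))
}

#' Plot a criterion table
#'
#' Bar chart of violation counts per criterion, filled by final
#' category.
#'
#' @param object A [criterion_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot criterion_table
#' @export
autoplot.criterion_table <- function(object, ...) {
  long <- object |>
    select("criterion", fraud = "fraud_n",
           potential_fraud = "potential_fraud_n", valid = "valid_n") |>
    tidyr::pivot_longer(-"criterion", names_to = "category",
                        values_to = "n")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$criterion,
                                                  .data$n, sum),
                               y = .data$n, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "entries violating criterion",
                  fill = "final category") +
    ggplot2::theme_minimal()
}

#' Plot the categorization flow of a pipeline
#'
#' Side-by-side bars of initial and final category counts.
#'
#' @param object A `fraud_pipeline`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fraud_pipeline
#' @export
autoplot.fraud_pipeline <- function(object, ...) {
  r <- object$records
  long <- bind_rows(
    tibble(stage = "initial", category = r$initial),
    tibble(stage = "final", category = r$final)
  ) |>
    count(.data$stage, .data$category)
  long$stage <- factor(long$stage, levels = c("initial", "final"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$n,
                                     fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "entries", fill = NULL) +
    ggplot2::theme_minimal()
}
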