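# surveyfraud

Point-based fraud detection for web-based survey research.

Web-based surveys that pay incentives attract two kinds of invalid
entries: ineligible respondents posing as eligible (misrepresentation
fraud) and eligible respondents submitting more than once (duplicate
fraud). IP addresses and GeoIP estimates cannot settle eligibility on
their own — smartphones, VPNs and NATs displace or collapse them, and
cohabiting respondents legitimately share devices and contact details.
`surveyfraud` implements a complete rule-based review protocol for this
setting, aimed at study teams running geographically restricted
web surveys and at methodologists evaluating fraud-detection rules.

## The method

Each entry at least 50% complete is scored against eight criteria; the
total

> T = 1·[geolocation outside area, no override] + 1·[business/invalid
> phone] + 1·[names mismatch within entry] + 1·[alternating
> letter/digit email] + 1·[≥2 contact items match a previous entry] +
> 2·[same name + ≥1 item match] + 2·[same date of birth + ≥1 item
> match] + 1·[survey < 5 minutes]

lies on a 0–10 scale. Entries with T ≥ 2 are categorized *fraud*,
T = 1 *potential fraud*, T = 0 *valid*. Potential-fraud entries are
recontacted: a verified response reclassifies them valid, an admission
or failed verification reclassifies them fraud, silence leaves them
potential. Geolocation is overridden — never flagged — when the entry
was completed at a recruitment event or its incentive is mailed to an
in-area address. Criteria whose evidence is missing are recorded as
not evaluable (0 points), distinct from clear.

The package ships the scoring engine and state machine, CSV ingest for
entries, phone directories and study configurations, a deterministic
canonical fixture reconstructing a published study's entry-level
violation patterns, a randomized labeled synthetic-respondent
generator, descriptive reports (criterion table, categorization flow,
IP-address sharing, geolocation breakdown), broom-style `tidy()` /
`glance()` methods, `autoplot()` methods, and a CLI
(`inst/cli/fraudcli`).

## Worked example

```r
library(surveyfraud)

fx   <- build_canonical_fixture()                       # 434 raw records
kept <- filter_completeness(fx$entries, fx$config)
#> filter_completeness: kept 414 of 434 entries (dropped 20 below 0.5)

pipe <- run_pipeline(kept, fx$config, directory = fx$phone_directory)
pipe
#> <fraud_pipeline> 414 entries
#>   initial: fraud 117, potential 72, valid 225
#>   final:   fraud 119, potential 42, valid 253
```

The 414 evaluable entries split 117 / 72 / 225 on scoring alone; after
recontact resolution (28 verified back to valid, 2 admitted
ineligibility, 42 silent) the final categorization is 119 fraudulent,
42 potentially fraudulent, 253 valid. Per-entry detail:

```r
head(tidy(pipe)[, c("entry_id", "total", "initial", "final")], 3)
#> # A tibble: 3 × 4
#>   entry_id total initial final
#>   <chr>    <dbl> <chr>   <chr>
#> 1 S0001        0 valid   valid
#> 2 S0002        0 valid   valid
#> 3 S0003        0 valid   valid
```

and an out-of-area entry with a business phone number scores 2 points
(fraud):

```r
card <- score_entry(kept[kept$entry_id == "S0298", ], kept[1:200, ],
                    fx$config, directory = fx$phone_directory)
card[, c("entry_id", "geolocation_status", "phone_status", "total")]
#> # A tibble: 1 × 4
#>   entry_id geolocation_status phone_status total
#>   <chr>    <chr>              <chr>        <dbl>
#> 1 S0298    violated           violated         2
```

Reports: `criterion_table()`, `flow_summary()`, `ip_share_report()`,
`geolocation_breakdown()`. Synthetic data with ground-truth labels:
`generate_synthetic(n, prevalence, seed)`; compare detector output to
labels with `evaluate_detector()`.

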