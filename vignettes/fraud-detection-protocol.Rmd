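---
title: "A point-based fraud-detection protocol for web-based surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A point-based fraud-detection protocol for web-based surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveyfraud)
```

## The problem

Web-based surveys are an effective way to reach hidden or stigmatized
populations, but the same anonymity that makes them attractive invites
two kinds of invalid entries: *misrepresentation fraud* (ineligible
respondents - often outside the study's geographic catchment - posing
as eligible to collect an incentive) and *duplicate fraud* (eligible
respondents submitting more than once). Neither the IP address nor the
geolocation derived from it can settle eligibility on its own:
smartphones, VPNs and network address translators routinely displace or
collapse IP-based locations, and legitimate cohabiting respondents can
share devices, addresses and phone numbers.

`surveyfraud` implements a manual-review protocol as reusable,
deterministic code: eight rule-based criteria scored on a 0-10 point
scale, a three-way categorization with thresholds, and a recontact
verification state machine that resolves suspicious entries.

## The scoring model

Each evaluable entry $i$ receives a total
$T_i = \sum_{c} p_c \, \mathbf{1}[\text{criterion } c \text{ violated}]$
over eight criteria $c$. Signals that could have an innocent
explanation carry $p_c = 1$; signals treated as independently
indicative of fraud carry $p_c = 2$:

| criterion | points | violated when |
|---|---|---|
| `geolocation` | 1 | IP-derived location outside the study area and no override |
| `phone` | 1 | number maps to a business/organization line or is invalid |
| `name_mismatch` | 1 | two name sources within the entry share no token |
| `email_pattern` | 1 | letter/digit runs alternate >= 3 times, no name-like run |
| `dup_two_items` | 1 | >= 2 contact items match a single previous entry |
| `dup_name_plus_item` | 2 | same full name and >= 1 item match a previous entry |
| `dup_dob_plus_item` | 2 | same date of birth and >= 1 item match a previous entry |
| `short_duration` | 1 | survey section completed in < 5 minutes |

Categorization: $T_i \ge 2$ is *fraud*, $T_i = 1$ is *potential
fraud* (suspicious but verifiable), $T_i = 0$ is *valid*. A criterion
whose evidence is absent is recorded as *not evaluable* and contributes
zero points; this is kept distinct from *clear* so that reports can
tabulate missingness.

Every knob is carried by `study_config()`: the point values, both
thresholds, the completeness floor (0.5, inclusive), the minimum survey
duration (5 minutes, strict), and the email-alternation minimum (3
transitions). The eligibility geography is a `study_area()` - a
country, a state, and a case-insensitively matched set of eligible
counties; the default is the 15-county Central Kentucky Bluegrass
region used throughout the package.

## Decisions the rules force, and how they were made

**Boundaries.** "At least 50% complete" is read inclusively
(completeness = 0.5 is kept); "completed in under 5 minutes" is read
strictly (exactly 5:00 is clear). Both follow the literal wording of
the protocol.

**Entry order.** The duplicate rules speak of a "previous" entry, so
a total order is needed. Entries are ordered by submission timestamp,
ties broken lexicographically by entry id; this is the only defensible
order and makes scoring deterministic. The chronologically first holder
of a contact item is never charged for later copies of that item.

**Geolocation resolution and overrides.** IP-derived estimates are
city/county-level inside the country at best and country-level abroad,
so the estimate is trusted only at its stated resolution: a matching
state with an unknown county is treated as inside the area (review
staff could not have excluded it either, and the protocol is explicit
that geolocation must not be used aggressively). Two overrides precede
the location test entirely, because they establish eligibility by other
means: observed participation at a recruitment event, and a mailed
incentive addressed inside the study area.

**Name matching.** Names are compared as lowercase token sets with
punctuation stripped, across up to four sources: three explicit fields
(consent, contact, incentive delivery) plus a candidate parsed from the
email local part (split on `.`, `_`, `-` and digit runs; alphabetic
tokens of length >= 2). A mismatch requires some pair of sources to
share *no* token, so "J. Doe" vs "John Doe" is consistent. No
phonetic or edit-distance matching and no nickname table: the protocol
gives no evidence of fuzzy matching, and adding it would manufacture
false mismatches the original staff never made.

**The email heuristic.** The bot-address description is
operationalized as: >= 3 transitions between maximal letter and digit
runs in the local part, *and* no alphabetic run of length >= 3 that
matches a token of the entry's explicit names (so `john12doe34@...`
belonging to a John Doe is not penalized). Beginning with a digit is
treated as evidence commonly co-occurring with the pattern, not as a
separate rule.

**Cross-entry rules.** The matchable items are phone (normalized to
bare digits, one leading country-code `1` dropped), email (lowercased)
and mailing address (lowercased street + city + county). A missing
field never matches. Each of the three duplicate rules requires a
*single* prior entry to supply all of its elements - a name match with
one prior and an item match with a different prior fires nothing - and
each rule fires at most once per entry, but the three rules may fire
against different priors and their points add. Adding rather than
taking a maximum is forced by the protocol's printed 0-10 scale
($6 \times 1 + 2 \times 2$).

**Not-evaluable bookkeeping for duplicates.** Missingness is recorded
per rule against the rule's distinctive evidence: `dup_two_items` is
not evaluable when all three contact items are absent,
`dup_name_plus_item` when the entry has no name fields, and
`dup_dob_plus_item` when the date of birth is absent. This per-rule
reading reproduces the published missingness column exactly; a blanket
"any required field missing" reading does not.

**The state machine.** Only potential-fraud entries can move:
`verified` reclassifies to valid, `admitted_ineligible` or
`failed_verification` to fraud, silence leaves them potentially
fraudulent; fraud and valid are absorbing. A `verified` response on a
fraud-categorized entry has no defined transition in the protocol (none
was ever observed), so it is flagged for manual review with a warning
rather than auto-reclassified. Recontact messages use the phone (SMS)
channel when a number is present, then email - the protocol lists the
channels without a rule, so the priority is configurable. Incentives
are payable exactly for final-valid entries; whether final
potential-fraud entries enter downstream analyses is left to the
caller.

## The canonical fixture

The protocol's published evaluation is a set of counts over a real
dataset that cannot be shared. `build_canonical_fixture()` reconstructs
a stand-in: 434 raw records whose per-entry violation patterns are
derived from the published marginals and cross-tabulations - which
criteria co-occur, which out-of-area geolocations are overridden and
how, which entries share IP addresses and with whom, and what each
recontacted entry answered. Field values (names, emails, phones,
addresses, dates of birth, durations) follow fixed index-based recipes
chosen so each entry violates exactly its block's criteria; the build
is seedless and byte-stable. Recovering the published counts from it
requires a correct implementation of every stage - the fixture encodes
*patterns*, and only the scoring rules, override logic, thresholds and
state machine turn those into the published numbers.

Three printed figures are deliberately not reproduced, because the
printed joint constraints admit no realization containing them:

* *"103 of 119 fraud entries violated >= 2 of the four identity
  criteria."* With 8 fraud entries violating none of the four and
  every name/DOB-duplicate rule requiring a companion criterion, at
  most 7 fraud entries can carry exactly one of the four; the tables
  force 104, which the fixture realizes and the test suite asserts.
* *"The observed score range was 0-5."* A 5-point entry implies a
  joint pattern not derivable from any printed table; the fixture's
  maximum is 4 (name-duplicate plus DOB-duplicate).
* *"18 of 414 matched personal information items of a previous
  entry."* The published per-rule counts (13, 6, 5) with the
  co-occurrence structure the other tables force yield a union of 16
  (still under 5%, as published).

One further accounting choice: the published partial-record arithmetic
(408 complete, 26 partials, 18 excluded, 6 included, 414 evaluable) is
internally inconsistent by two records. The fixture follows the flow
counts, which every downstream figure depends on: 434 raw records, 20
partials below the 50% floor, 414 evaluable.

All 82 overridden out-of-area entries are placed in the final-valid
group (the publication does not say whether any fraud or potential
entry had an overriding address; valid placement is the conservative
reading), and the missing-field plan reproduces the published
missingness column (93 blank phones, 16 entries with no name fields,
98 without email, 71 with fewer than two name sources, 67 with no
contact items, 5 without date of birth).

## The synthetic generator

`generate_synthetic()` provides randomized, labeled datasets for
property testing, drawing each entry from five archetypes:
`honest_local` (clean in-area entries), `out_of_area`
(misrepresentation fraud: ineligible geolocation, with configurable
probabilities of business phone numbers, internal name mismatches and
bot-style emails), `bot` (alternating emails, short durations, mostly
out-of-area), `duplicate` (reuses the phone and email of a random
earlier entry, sometimes its name or date of birth), and
`cohabiting_pair` (the legitimate-sharing case: shared address and
phone, different names and dates of birth, verifies on recontact). The
default prevalences (0.60, 0.25, 0.08, 0.04, 0.03) echo the study's
observed composition of roughly six in ten valid entries with
misrepresentation dominating fraud. Ground truth labels mark
out-of-area, bot and duplicate entries as fraud.

The generator emulates the *signals the rules read*, not real survey
content: it produces no item-level responses, no realistic name/email
marginals (values come from small pools with index suffixes), no
missingness beyond what the archetypes imply, and no adversary who
adapts - bots always alternate, duplicates always reuse verbatim.
Passing tests on synthetic data therefore show that the rules fire
when and only when their defining patterns are present, not that the
protocol would achieve any particular sensitivity on real fraud.

## Numerical and degenerate-input choices

Timestamps are ISO-8601 UTC and dates ISO-8601 calendar dates; files
are UTF-8 CSV. Durations are computed from the survey section
timestamps only. Malformed rows and duplicate ids fail loudly with the
row number; blank cells are missing optionals. The phone directory is
closed-world: a number it does not list is invalid (the offline
stand-in for the live reverse-lookup the protocol used). Percentages in
reports are rounded half-up to one decimal, matching table formatting
conventions. Empty inputs flow through every stage (empty scorecards,
all-zero tables, zero-resolution flows). Scoring is a pure function of
its inputs: repeated evaluation gives identical results, and the test
suite asserts idempotence, score bounds, override monotonicity,
missing-data neutrality over the contact fields, first-occurrence
safety for duplicates, and conservation of entries across
categorization stages.

One documented edge of missing-data neutrality: blanking an entry's
*name fields* can in principle raise its score, because a name-like
email otherwise excused by the name-run exemption becomes a bare
alternating pattern. This is the rule behaving as specified - the
exemption exists only when a name is present to match - and the
neutrality property is therefore asserted over the contact items
(phone, email, date of birth, names as consistency sources, and the
mailing address of entries not using mailed payment).

## Problem sizes

The test suite runs the full pipeline on the 434-record fixture (the
scale of the original study), property checks on synthetic datasets of
150-400 entries, a prevalence convergence check on 10,000 generated
labels (tolerance 2%), and a brute-force confusion-matrix cross-check
at n = 20. Everything completes in well under a minute on one core.

## A worked run

```{r pipeline}
fx <- build_canonical_fixture()
kept <- filter_completeness(fx$entries, fx$config)
pipe <- run_pipeline(kept, fx$config, directory = fx$phone_directory)
pipe
glance(pipe)
criterion_table(kept, pipe$scorecards, pipe$records)
ip_share_report(kept, pipe$records)
geolocation_breakdown(kept, pipe$scorecards, fx$config$study_area)
```

## Limitations

The protocol is a manual-review procedure made executable, not a
learned detector: it will not catch fraud that leaves none of the eight
signals, and its phone criterion inherits whatever the directory knows.
Name comparison is exact-token; culturally distinct name orders,
transliteration variants and nicknames are out of scope. The
geolocation criterion depends entirely on the upstream GeoIP estimate's
stated resolution. The fixture reproduces published *counts*, not the
study's respondents; conclusions about real-world operating
characteristics require real data.
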