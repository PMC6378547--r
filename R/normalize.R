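# Normalization helpers shared by the criteria engine and the
# cross-entry duplicate rules.

#' Normalize phone numbers to bare digit strings
#'
#' Strips every non-digit character and drops a single leading
#' country-code "1" from 11-digit numbers, so that directory lookups and
#' cross-entry comparisons are robust to formatting.
#'
#' @param x Character vector of phone numbers (NA allowed).
#' @return Character vector of digit strings (NA where input is missing
#'   or contains no digits).
#' @export
normalize_phone <- function(x) {
  digits <- gsub("[^0-9]", "", x %||% NA_character_)
  digits[!is.na(digits) & nchar(digits) == 11L &
           substr(digits, 1L, 1L) == "1"] <-
    substr(digits[!is.na(digits) & nchar(digits) == 11L &
                    substr(digits, 1L, 1L) == "1"], 2L, 11L)
  digits[!is.na(digits) & digits == ""] <- NA_character_
  digits
}

normalize_email <- function(x) {
  out <- tolower(trimws(x))
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

# Lowercased street+city+county key for cross-entry address matching.
normalize_address <- function(street, city, county) {
  parts <- cbind(street, city, county)
  key <- apply(parts, 1L, function(p) {
    p <- p[!is.na(p) & trimws(p) != ""]
    if (length(p) == 0L) return(NA_character_)
    tolower(gsub("\\s+", " ", trimws(paste(p, collapse = " "))))
  })
  as.character(key)
}

# One free-text name -> sorted unique lowercase tokens (punctuation
# stripped). Returns character(0) for blank/missing input.
name_tokens <- function(x) {
  if (is.na(x) || trimws(x) == "") return(character(0))
  x <- tolower(gsub("[^a-zA-Z ]", " ", x))
  toks <- strsplit(trimws(gsub("\\s+", " ", x)), " ")[[1]]
  sort(unique(toks[nchar(toks) > 0L]))
}

email_local <- function(email) {
  if (is.na(email)) return(NA_character_)
  sub("@.*$", "", tolower(trimws(email)))
}

# Candidate name parsed from an email local part: split on '.', '_',
# '-' and digit runs; keep alphabetic tokens of length >= 2.
email_name_candidate <- function(email) {
  local <- email_local(email)
  if (is.na(local)) return(character(0))
  toks <- strsplit(gsub("[0-9]+", " ", gsub("[._-]+", " ", local)),
                   "\\s+")[[1]]
  toks <- toks[grepl("^[a-z]+$", toks) & nchar(toks) >= 2L]
  sort(unique(toks))
}

# Number of transitions between maximal letter-runs and digit-runs in
# the email local part (non-alphanumerics ignored). "a12bcd34e" -> 4.
email_alternations <- function(email) {
  local <- email_local(email)
  if (is.na(local)) return(NA_integer_)
  chars <- strsplit(gsub("[^a-z0-9]", "", local), "")[[1]]
  if (length(chars) == 0L) return(0L)
  type <- ifelse(grepl("[0-9]", chars), "d", "l")
  runs <- rle(type)$values
  length(runs) - 1L
}

# Maximal alphabetic runs of the local part (used for the name-like-run
# exemption of the email-pattern heuristic).
email_letter_runs <- function(email) {
  local <- email_local(email)
  if (is.na(local)) return(character(0))
  runs <- regmatches(local, gregexpr("[a-z]+", local))[[1]]
  unique(runs)
}
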