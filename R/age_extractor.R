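# Self-reported age extraction from tweet text. Conservative, first-person
# anchored patterns; a user's age comes from their most recent age-bearing
# tweet, with a hard >= 13 floor.

AGE_GROUPS <- c("13-24", "25-34", "35-44", "45-54", "55+")

# capture-group patterns; names are the shipped pattern ids
AGE_PATTERNS <- c(
  first_person_am = "(?i)\\b(?:i['’]?m|i\\s+am|im)\\s+(\\d{1,3})\\b(?!\\s*(?:%|percent))",
  years_old = "(?i)\\b(\\d{1,3})\\s*(?:years?|yrs?)[\\s-]*old\\b",
  turned = "(?i)\\bturn(?:ed|ing|s)?\\s+(\\d{1,3})\\b(?!\\s*(?:%|percent))",
  birthday = "(?i)\\bmy\\s+(\\d{1,3})\\s*(?:st|nd|rd|th)\\s+b(?:irth)?day\\b"
)
BIRTH_YEAR_RE <- "(?i)\\bborn\\s+in\\s+((?:19|20)\\d{2})\\b"

#' Age-extraction configuration
#'
#' @param include_birth_year Also recognize "born in YYYY" and compute age
#'   against the tweet timestamp. Off by default: birth-year arithmetic is
#'   an inference, not a direct self-report.
#' @return A list of class `age_config`.
#' @export
age_config <- function(include_birth_year = FALSE) {
  structure(list(include_birth_year = include_birth_year), class = "age_config")
}

#' Extract self-reported age mentions from a text
#'
#' Recognizes first-person age patterns: "I'm/I am N (years old)", "N years
#' old" in a sentence containing a first-person pronoun, "turned/turning
#' N", and ordinal birthday forms ("my Nth birthday"). "I'm 100% sure"
#' style percentages are guarded against. Values outside \[0, 130\] are
#' discarded. Overlapping pattern hits at the same position are de-duplicated.
#'
#' @param text Tweet text.
#' @param tweet_id,created_at Provenance attached to each mention.
#' @param config An [age_config()].
#' @return A tibble `tweet_id`, `value`, `pattern_id`, `created_at`,
#'   `start` (text order), possibly empty.
#' @examples
#' extract_age_mentions("I'm 24 years old and tired")
#' @export
extract_age_mentions <- function(text, tweet_id = NA_character_,
                                 created_at = as.POSIXct(NA, tz = "UTC"),
                                 config = age_config()) {
  out <- list()
  for (pid in names(AGE_PATTERNS)) {
    loc <- stringr::str_locate_all(text, AGE_PATTERNS[[pid]])[[1]]
    if (nrow(loc) == 0) next
    m <- stringr::str_match_all(text, AGE_PATTERNS[[pid]])[[1]]
    vals <- suppressWarnings(as.integer(m[, 2]))
    if (pid == "years_old") {
      # require a first-person pronoun in the same sentence
      sb <- sentence_bounds(text)
      keep <- vapply(seq_len(nrow(loc)), function(i) {
        row <- which(sb[, "start"] <= loc[i, 1] & sb[, "stop"] >= loc[i, 1])
        if (length(row) == 0) return(FALSE)
        sent <- stringr::str_sub(text, sb[row[1], "start"], sb[row[1], "stop"])
        stringr::str_detect(sent, FIRST_PERSON_RE)
      }, logical(1))
      loc <- loc[keep, , drop = FALSE]
      vals <- vals[keep]
    }
    if (nrow(loc) == 0) next
    out[[pid]] <- tibble::tibble(
      tweet_id = tweet_id, value = vals, pattern_id = pid,
      created_at = created_at, start = loc[, 1], stop = loc[, 2]
    )
  }
  if (isTRUE(config$include_birth_year)) {
    m <- stringr::str_match_all(text, BIRTH_YEAR_RE)[[1]]
    loc <- stringr::str_locate_all(text, BIRTH_YEAR_RE)[[1]]
    if (nrow(m) > 0 && !is.na(created_at)) {
      yr <- as.integer(format(created_at, "%Y"))
      out[["birth_year"]] <- tibble::tibble(
        tweet_id = tweet_id, value = yr - as.integer(m[, 2]),
        pattern_id = "birth_year", created_at = created_at,
        start = loc[, 1], stop = loc[, 2]
      )
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(tweet_id = character(), value = integer(),
                          pattern_id = character(),
                          created_at = as.POSIXct(character(), tz = "UTC"),
                          start = integer()))
  }
  res <- res[res$value >= 0 & res$value <= 130, , drop = FALSE]
  # the same digits can be hit by several patterns ("I'm 24 years old");
  # keep one mention per overlapping region, earlier pattern wins
  prio <- match(res$pattern_id, c(names(AGE_PATTERNS), "birth_year"))
  res <- res[order(prio), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(res)) > i)
    overlap <- later[res$start[later] <= res$stop[i] & res$stop[later] >= res$start[i]]
    keep[overlap] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  res$stop <- NULL
  res
}

#' Assign an age to its demographic group
#'
#' Bins are total and disjoint over \[13, 130\]: 13-24, 25-34, 35-44,
#' 45-54, 55+.
#'
#' @param age Integer vector of ages >= 13.
#' @return Character vector of group labels.
#' @export
age_group <- function(age) {
  as.character(cut(age, breaks = c(13, 25, 35, 45, 55, 131),
                   labels = AGE_GROUPS, right = FALSE))
}

#' Resolve one user's age from their mentions
#'
#' Takes the mention from the most recent tweet (ties within a tweet, or on
#' timestamp: the largest value wins, guarding against "I'm 5 foot ... I'm
#' 24"). Ages below 13 yield no report.
#'
#' @param mentions Tibble of age mentions for a single user, with a
#'   `user_id` column.
#' @return A one-row tibble `user_id`, `age`, `source_tweet_id`,
#'   `age_group`, or `NULL`.
#' @export
resolve_user_age <- function(mentions) {
  if (is.null(mentions) || nrow(mentions) == 0) return(NULL)
  if (!"user_id" %in% names(mentions)) {
    abort("`mentions` must carry a user_id column.",
          class = "selfreportr_contract_error")
  }
  if (length(unique(mentions$user_id)) > 1) {
    abort("`mentions` must all belong to one user.",
          class = "selfreportr_contract_error")
  }
  m <- mentions[order(mentions$created_at, mentions$value,
                      decreasing = TRUE), , drop = FALSE][1, ]
  if (is.na(m$value) || m$value < 13) return(NULL)
  tibble::tibble(
    user_id = m$user_id, age = as.integer(m$value),
    source_tweet_id = m$tweet_id, age_group = age_group(m$value)
  )
}

# Vectorized sweep: extract mentions over a record table and resolve one
# age per user. Returns tibble user_id, age, source_tweet_id, age_group.
extract_user_ages <- function(records, config = age_config()) {
  empty <- tibble::tibble(user_id = character(), age = integer(),
                          source_tweet_id = character(), age_group = character())
  if (nrow(records) == 0) return(empty)
  # cheap pre-filter: only texts containing digits can carry a mention
  cand <- records[stringr::str_detect(records$text, "\\d"), , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  mentions <- dplyr::bind_rows(lapply(seq_len(nrow(cand)), function(i) {
    m <- extract_age_mentions(cand$text[i], cand$tweet_id[i],
                              cand$created_at[i], config)
    if (nrow(m) > 0) m$user_id <- cand$user_id[i]
    m
  }))
  if (nrow(mentions) == 0) return(empty)
  mentions |>
    dplyr::group_by(.data$user_id) |>
    dplyr::group_split() |>
    lapply(resolve_user_age) |>
    dplyr::bind_rows()
}
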