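# Retweet and reported-speech removal. Retweets are dropped as a blanket
# pre-filter; reported speech is judged at match time because it needs the
# candidate span.

ATTRIBUTION_VERBS <- c(
  "said", "says", "say", "told", "tells", "wrote", "writes",
  "tweeted", "tweets", "posted", "announced", "reported", "claimed", "claims"
)

FIRST_PERSON_RE <- "(?i)\\b(?:i|i['’]m|i['’]ve|i['’]d|im|me|my|mine|we|our|ours|us)\\b"
URL_TAIL_RE <- "https?://\\S+[[:punct:]]*\\s*$"

#' Reported-speech detector configuration
#'
#' Three independently toggleable rules: `quotation` (the candidate span
#' lies inside a quotation-mark-delimited region), `attribution` (the
#' sentence containing the span ends with an attribution verb such as
#' said/says/told/wrote/tweeted, with an optional subject), and `headline`
#' (the text reads like a news headline: no first-person pronoun anywhere,
#' ends with a URL, and title-case word density at or above
#' `titlecase_threshold`).
#'
#' @param quotation,attribution,headline Logical; enable each rule.
#' @param titlecase_threshold Minimum fraction of capitalized words for the
#'   headline rule. Headlines are often sentence-case, so the default is a
#'   permissive 0.1; the URL and pronoun clauses carry the specificity.
#' @return A list of class `rs_config`.
#' @export
rs_config <- function(quotation = TRUE, attribution = TRUE, headline = TRUE,
                      titlecase_threshold = 0.1) {
  stopifnot(is.logical(quotation), is.logical(attribution), is.logical(headline),
            is.numeric(titlecase_threshold),
            titlecase_threshold >= 0, titlecase_threshold <= 1)
  structure(
    list(quotation = quotation, attribution = attribution, headline = headline,
         titlecase_threshold = titlecase_threshold),
    class = "rs_config"
  )
}

#' Is a record a retweet?
#'
#' True iff the normalized retweet flag is set. Quote-tweets are not
#' retweets; their quoted content is handled by the reported-speech rules.
#'
#' @param record A one-row (or multi-row) tibble of normalized records.
#' @return Logical vector.
#' @export
is_retweet <- function(record) {
  record$is_retweet
}

# Pair quotation marks into character regions. Straight double quotes pair
# sequentially; curly doubles and curly singles pair by open/close type
# (a lone right single quote is an apostrophe, not a closer). Unbalanced
# openers close at end-of-text.
quoted_regions <- function(text) {
  chars <- stringr::str_split(text, "")[[1]]
  n <- length(chars)
  regions <- list()
  add <- function(s, e) regions[[length(regions) + 1]] <<- c(s, e)

  straight <- which(chars == '"')
  if (length(straight) > 0) {
    k <- length(straight) %/% 2
    for (j in seq_len(k)) add(straight[2 * j - 1], straight[2 * j])
    if (length(straight) %% 2 == 1) add(straight[length(straight)], n)
  }
  pair_typed <- function(open_ch, close_ch) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (chars[i] == open_ch) {
        stack <- c(stack, i)
      } else if (chars[i] == close_ch && length(stack) > 0) {
        add(stack[length(stack)], i)
        stack <- stack[-length(stack)]
      }
    }
    for (s in stack) add(s, n)
  }
  pair_typed("“", "”") # curly doubles
  pair_typed("‘", "’") # curly singles; stray closers are apostrophes
  regions
}

# clause-level diagnostics for the headline rule (used by tests)
headline_clauses <- function(text, titlecase_threshold = 0.1) {
  no_first_person <- !stringr::str_detect(text, FIRST_PERSON_RE)
  ends_with_url <- stringr::str_detect(text, URL_TAIL_RE)
  stripped <- stringr::str_remove_all(text, "https?://\\S+")
  words <- stringr::str_split(stringr::str_trim(stripped), "\\s+")[[1]]
  words <- words[stringr::str_detect(words, "^[[:alpha:]]")]
  density <- if (length(words) == 0) 0 else mean(stringr::str_detect(words, "^[A-Z]"))
  list(
    no_first_person = no_first_person,
    ends_with_url = ends_with_url,
    titlecase_density = density,
    titlecase_ok = density >= titlecase_threshold
  )
}

sentence_bounds <- function(text) {
  # half-open sentence intervals split on terminal punctuation runs
  ends <- stringr::str_locate_all(text, "[.!?]+")[[1]]
  n <- nchar(text)
  starts <- c(1L, if (nrow(ends) > 0) ends[, 2] + 1L)
  starts <- starts[starts <= n]
  stops <- c(starts[-1] - 1L, n)
  cbind(start = starts, stop = stops)
}

#' Detect reported speech around a candidate match span
#'
#' Flags a candidate self-report as reported speech when (a) the span lies
#' inside a quotation-mark-delimited region (straight or curly quotes;
#' unbalanced quotes close at end-of-text), (b) the sentence containing the
#' span ends with an attribution verb pattern, or (c) the whole text matches
#' the headline heuristic (see [rs_config()]).
#'
#' @param text The full tweet text.
#' @param span Half-open character interval `c(start, end)` (1-based) of the
#'   candidate match within `text`.
#' @param config An [rs_config()].
#' @return A list with `reported` (logical) and `trigger` (`"quotation"`,
#'   `"attribution"`, `"headline"`, or `NA`).
#' @examples
#' detect_reported_speech('"I am a gay man," he said.', c(2, 16))
#' @export
detect_reported_speech <- function(text, span, config = rs_config()) {
  n <- nchar(text)
  if (!is.numeric(span) || length(span) != 2 || is.na(span[1]) || is.na(span[2]) ||
      span[1] < 1 || span[2] <= span[1] || span[2] > n + 1) {
    abort("`span` must be a valid half-open character interval within `text`.",
          class = "selfreportr_contract_error")
  }
  s <- span[1]
  e <- span[2] - 1 # inclusive end

  if (isTRUE(config$quotation)) {
    quote_chars <- c('"', "“", "”", "‘", "’")
    for (reg in quoted_regions(text)) {
      closer_is_mark <- stringr::str_sub(text, reg[2], reg[2]) %in% quote_chars
      inside <- if (closer_is_mark) s > reg[1] && e < reg[2] else s > reg[1] && e <= reg[2]
      if (inside) {
        return(list(reported = TRUE, trigger = "quotation"))
      }
    }
  }

  if (isTRUE(config$attribution)) {
    sb <- sentence_bounds(text)
    row <- which(sb[, "start"] <= s & sb[, "stop"] >= s)
    if (length(row) > 0) {
      sent <- stringr::str_sub(text, sb[row[1], "start"], sb[row[1], "stop"])
      verb_alt <- paste(ATTRIBUTION_VERBS, collapse = "|")
      attrib_re <- paste0(
        "(?i)[,—–-]?\\s*[\"”'’]*\\s*(?:\\b[[:alpha:]@#]+\\s+)?",
        "\\b(?:", verb_alt, ")\\b[\\s\"'”’]*[.!?]*\\s*$"
      )
      if (stringr::str_detect(sent, attrib_re)) {
        return(list(reported = TRUE, trigger = "attribution"))
      }
    }
  }

  if (isTRUE(config$headline)) {
    hc <- headline_clauses(text, config$titlecase_threshold)
    if (hc$no_first_person && hc$ends_with_url && hc$titlecase_ok) {
      return(list(reported = TRUE, trigger = "headline"))
    }
  }

  list(reported = FALSE, trigger = NA_character_)
}

#' Remove retweets from a stream
#'
#' Blanket pre-filter: every input record receives exactly one decision;
#' retweets are dropped, everything else is retained. Reported speech is
#' span-conditional and therefore judged later, at match time (see
#' [detect_reported_speech()] and [classify_user()]).
#'
#' @param records A tibble of normalized records.
#' @return A list with `retained` (records with verdict `retain`, order
#'   preserved) and `decisions` (tibble `tweet_id`, `verdict`, `trigger`).
#' @export
filter_stream <- function(records) {
  rt <- if (nrow(records) == 0) logical(0) else is_retweet(records)
  decisions <- tibble::tibble(
    tweet_id = records$tweet_id,
    verdict = ifelse(rt, "drop_retweet", "retain"),
    trigger = ifelse(rt, "retweet_flag", NA_character_)
  )
  list(retained = records[!rt, , drop = FALSE], decisions = decisions)
}
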