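# Template grammar for first-person self-report matching. Templates are
# regex skeletons with placeholders {identity}, {person}, {people}, {mod};
# spaces match any whitespace run, "'" matches straight or curly
# apostrophes, and the whole pattern is word-bounded and case-insensitive.
# Tweet templates require a first-person anchor; profile templates accept a
# bare identity+person collocation because profile text is self-descriptive
# by convention.

MOD_GAP_RE <- "(?:[\\w’-]+\\s+){0,2}" # up to two intervening modifier words

TRANSNB_RE <- "(?i)\\b(?:trans|transgender|transsexual|nonbinary|non[- ]?binary|enby|genderqueer|genderfluid)\\b"
THIRD_PERSON_GUARD_RE <- "(?i)\\b(?:his|her|their)\\b(?:\\s+[\\w'’-]+){0,3}\\s*$"

#' Default self-report pattern configuration
#'
#' Reads the shipped YAML pattern document (identity terms, person terms,
#' and the template inventory for the tweet and profile channels). Users
#' can edit a copy and pass it to [compile_pattern_set()].
#'
#' @param path Optional path to a YAML pattern document; defaults to the
#'   file shipped with the package.
#' @return A named list with `identity_terms`, `person_terms`,
#'   `people_terms`, `tweet_templates`, `profile_templates`.
#' @export
default_pattern_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "patterns_default.yaml",
                                package = "selfreportr")
  cfg <- yaml::read_yaml(path)
  cfg$tweet_templates <- lapply(cfg$tweet_templates, function(t) t)
  cfg
}

template_placeholders <- function(template) {
  unique(stringr::str_match_all(template, "\\{(\\w+)\\}")[[1]][, 2])
}

finalize_regex <- function(pattern) {
  pattern <- stringr::str_replace_all(pattern, "'", "['’]")
  pattern <- stringr::str_replace_all(pattern, " ", "\\\\s+")
  paste0("\\b", pattern, "\\b")
}

substitute_terms <- function(template, identity, person, people) {
  out <- template
  out <- stringr::str_replace_all(out, stringr::fixed("{identity}"),
                                  paste0("(?:", identity, ")"))
  out <- stringr::str_replace_all(out, stringr::fixed("{person}"),
                                  paste0("(?:", person, ")"))
  out <- stringr::str_replace_all(out, stringr::fixed("{people}"),
                                  paste0("(?:", people, ")"))
  out <- stringr::str_replace_all(out, stringr::fixed("{mod}"), MOD_GAP_RE)
  out
}

#' Compile a pattern set
#'
#' Expands each template against the identity/person term lists: a template
#' naming both an identity and a person placeholder expands to the full
#' cross-product of surface forms (N identity terms x M person terms).
#' Compilation is deterministic, case-insensitive, and word-bounded, so
#' short terms such as "bi" only match as standalone tokens.
#'
#' @param config A pattern configuration (see [default_pattern_config()]).
#' @return An object of class `pattern_set`: the configuration, a tibble of
#'   expanded surface forms (`surface`), and one combined matcher regex per
#'   template (`matchers`), ordered by template list order for tie-breaking.
#' @examples
#' ps <- compile_pattern_set()
#' ps
#' @export
compile_pattern_set <- function(config = default_pattern_config()) {
  for (key in c("identity_terms", "person_terms", "people_terms")) {
    if (length(config[[key]]) == 0 || !all(nzchar(config[[key]]))) {
      abort(paste0("Pattern config error: `", key, "` must be a non-empty list."),
            class = "selfreportr_config_error")
    }
  }
  channels <- list(tweet = config$tweet_templates, profile = config$profile_templates)
  for (ch in names(channels)) {
    if (length(channels[[ch]]) == 0) {
      abort(paste0("Pattern config error: at least one ", ch, " template is required."),
            class = "selfreportr_config_error")
    }
  }

  surface <- list()
  matchers <- list()
  order_i <- 0L
  for (ch in names(channels)) {
    for (tmpl_id in names(channels[[ch]])) {
      template <- channels[[ch]][[tmpl_id]]
      ph <- template_placeholders(template)
      unknown <- setdiff(ph, c("identity", "person", "people", "mod"))
      if (length(unknown) > 0) {
        abort(paste0("Pattern config error: unknown placeholder {", unknown[1],
                     "} in template `", tmpl_id, "`."),
              class = "selfreportr_config_error")
      }
      order_i <- order_i + 1L
      ids <- if ("identity" %in% ph) config$identity_terms else NA_character_
      ppl <- if ("person" %in% ph) {
        config$person_terms
      } else if ("people" %in% ph) {
        config$people_terms
      } else {
        NA_character_
      }
      grid <- expand.grid(identity = ids, person = ppl,
                          stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
      grid$regex <- vapply(seq_len(nrow(grid)), function(i) {
        finalize_regex(substitute_terms(
          template,
          identity = grid$identity[i],
          person = if ("person" %in% ph) grid$person[i] else "",
          people = if ("people" %in% ph) grid$person[i] else ""
        ))
      }, character(1))
      surface[[length(surface) + 1]] <- tibble::tibble(
        channel = ch, template_id = tmpl_id, order = order_i,
        identity = grid$identity, person = grid$person, regex = grid$regex
      )
      combined <- finalize_regex(substitute_terms(
        template,
        identity = paste(config$identity_terms, collapse = "|"),
        person = paste(config$person_terms, collapse = "|"),
        people = paste(config$people_terms, collapse = "|")
      ))
      matchers[[length(matchers) + 1]] <- tibble::tibble(
        channel = ch, template_id = tmpl_id, order = order_i, regex = combined
      )
    }
  }

  structure(
    list(config = config,
         surface = dplyr::bind_rows(surface),
         matchers = dplyr::bind_rows(matchers)),
    class = "pattern_set"
  )
}

#' @export
print.pattern_set <- function(x, ...) {
  n_t <- sum(x$surface$channel == "tweet")
  n_p <- sum(x$surface$channel == "profile")
  cat("<pattern_set>\n")
  cat("  identity terms:", length(x$config$identity_terms),
      "| person terms:", length(x$config$person_terms), "\n")
  cat("  surface forms: ", n_t, " (tweet) + ", n_p, " (profile)\n", sep = "")
  cat("  templates:", paste(x$matchers$template_id, collapse = ", "), "\n")
  invisible(x)
}

# Vectorized leftmost match over many texts for one channel. Returns a
# tibble with one row per text: start/end (half-open, NA when no match)
# and template_id. Ties on start position resolve by template list order.
match_texts <- function(texts, ps, channel, mode = "default") {
  n <- length(texts)
  best_start <- rep(NA_integer_, n)
  best_end <- rep(NA_integer_, n)
  best_template <- rep(NA_character_, n)
  mt <- ps$matchers[ps$matchers$channel == channel, , drop = FALSE]
  mt <- mt[order(mt$order), , drop = FALSE]
  for (i in seq_len(nrow(mt))) {
    loc <- stringr::str_locate(texts, stringr::regex(mt$regex[i], ignore_case = TRUE))
    better <- !is.na(loc[, 1]) & (is.na(best_start) | loc[, 1] < best_start)
    best_start[better] <- loc[better, 1]
    best_end[better] <- loc[better, 2] + 1L # half-open
    best_template[better] <- mt$template_id[i]
  }
  out <- tibble::tibble(start = best_start, end = best_end,
                        template_id = best_template)
  if (mode == "strict") {
    hit <- !is.na(out$start)
    if (channel == "tweet") {
      # exclude matches preceded by a third-person possessive phrase
      prefix <- stringr::str_sub(texts, 1, pmax(out$start - 1, 0))
      excluded <- hit & stringr::str_detect(prefix, THIRD_PERSON_GUARD_RE)
    } else {
      excluded <- hit & stringr::str_detect(texts, TRANSNB_RE)
    }
    out$start[excluded] <- NA_integer_
    out$end[excluded] <- NA_integer_
    out$template_id[excluded] <- NA_character_
  }
  out
}

match_to_result <- function(text, m, channel) {
  if (is.na(m$start)) return(NULL)
  tibble::tibble(
    channel = channel,
    start = m$start,
    end = m$end,
    template_id = m$template_id,
    matched_text = stringr::str_sub(text, m$start, m$end - 1)
  )
}

#' Match a tweet text against the tweet-channel templates
#'
#' Returns the leftmost match of any tweet-channel surface pattern, or
#' `NULL`. Tweet templates require a first-person anchor, so identity terms
#' without first-person context ("I love my gay friends") do not match. In
#' `strict` mode, matches preceded by a third-person possessive phrase
#' ("... his identity as a gay male") are additionally excluded — an
#' extension beyond the default operating point, which intentionally keeps
#' such matches so that measured precision reflects the annotation layer.
#'
#' @param text Full tweet text.
#' @param ps A [compile_pattern_set()] result.
#' @param mode `"default"` or `"strict"`.
#' @return A one-row tibble (`channel`, `start`, `end` half-open,
#'   `template_id`, `matched_text`) or `NULL`.
#' @export
match_tweet_text <- function(text, ps, mode = "default") {
  m <- match_texts(text, ps, "tweet", mode)
  match_to_result(text, m[1, ], "tweet")
}

#' Match a user profile against the profile-channel templates
#'
#' Searches the profile description first, then the display name. Profile
#' templates do not require a first-person anchor. In `strict` mode,
#' profiles mentioning transgender/nonbinary identity terms are excluded
#' (the dominant false-positive family under the default operating point).
#'
#' @param user A one-row tibble from [consolidate_users()] (fields
#'   `user_description`, `user_name`).
#' @param ps A [compile_pattern_set()] result.
#' @param mode `"default"` or `"strict"`.
#' @return A one-row tibble as in [match_tweet_text()] (with an extra
#'   `field` column naming the matched profile field) or `NULL`.
#' @export
match_profile <- function(user, ps, mode = "default") {
  for (field in c("user_description", "user_name")) {
    text <- user[[field]]
    if (is.na(text) || !nzchar(text)) next
    if (mode == "strict" &&
        stringr::str_detect(paste(user$user_description, user$user_name),
                            TRANSNB_RE)) {
      return(NULL)
    }
    m <- match_texts(text, ps, "profile", mode)
    res <- match_to_result(text, m[1, ], "profile")
    if (!is.null(res)) {
      res$field <- field
      return(res)
    }
  }
  NULL
}

#' Classify one user's evidence channel
#'
#' Given a user's retweet-filtered tweets and consolidated profile, decides
#' whether the user enters the cohort and through which channel: `tweet` if
#' any tweet match survives the reported-speech rules, `profile` if the
#' profile matches, `both` if both. The earliest surviving tweet match is
#' recorded as provenance.
#'
#' @param tweets Tibble of normalized records, all from the same user.
#' @param user One-row tibble from [consolidate_users()].
#' @param ps A [compile_pattern_set()] result.
#' @param rs An [rs_config()].
#' @param mode `"default"` or `"strict"`.
#' @return A one-row tibble (`user_id`, `evidence`, `source_tweet_id`,
#'   `template_id`) or `NULL` when there is no evidence.
#' @export
classify_user <- function(tweets, user, ps, rs = rs_config(), mode = "default") {
  if (nrow(tweets) > 0) {
    uids <- unique(tweets$user_id)
    if (length(uids) > 1) {
      abort("`tweets` must all belong to one user.",
            class = "selfreportr_contract_error")
    }
    if (!is.null(user) && nrow(user) == 1 && uids != user$user_id) {
      abort("`tweets` and `user` disagree on user_id.",
            class = "selfreportr_contract_error")
    }
  }
  tweet_hit <- NULL
  if (nrow(tweets) > 0) {
    tweets <- tweets[!tweets$is_retweet, , drop = FALSE]
    tweets <- tweets[order(tweets$created_at, tweets$tweet_id), , drop = FALSE]
    for (i in seq_len(nrow(tweets))) {
      m <- match_tweet_text(tweets$text[i], ps, mode)
      if (is.null(m)) next
      rsd <- detect_reported_speech(tweets$text[i], c(m$start, m$end), rs)
      if (!rsd$reported) {
        tweet_hit <- list(tweet_id = tweets$tweet_id[i], template_id = m$template_id)
        break
      }
    }
  }
  profile_hit <- if (!is.null(user) && nrow(user) == 1) {
    match_profile(user, ps, mode)
  } else {
    NULL
  }
  if (is.null(tweet_hit) && is.null(profile_hit)) return(NULL)
  evidence <- if (!is.null(tweet_hit) && !is.null(profile_hit)) {
    "both"
  } else if (!is.null(tweet_hit)) {
    "tweet"
  } else {
    "profile"
  }
  uid <- if (!is.null(user) && nrow(user) == 1) user$user_id else unique(tweets$user_id)
  tibble::tibble(
    user_id = uid,
    evidence = evidence,
    source_tweet_id = if (!is.null(tweet_hit)) tweet_hit$tweet_id else NA_character_,
    template_id = if (!is.null(tweet_hit)) tweet_hit$template_id else profile_hit$template_id
  )
}
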