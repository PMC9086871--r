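# Stream ingestion: normalize Twitter JSON dialects into a flat record table.

TWITTER_V1_TIME <- "%a %b %d %H:%M:%S %z %Y"

#' Sentinel timestamp assigned to records with unparseable dates
#'
#' Records whose `created_at` cannot be parsed are kept (dropping them would
#' silently shrink the cohort) and stamped with this minimal instant; a
#' warning is raised when it is used.
#'
#' @return A length-one `POSIXct` (1970-01-01 00:00:00 UTC).
#' @export
sentinel_time <- function() {
  as.POSIXct("1970-01-01 00:00:00", tz = "UTC")
}

parse_created_at <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x) || !nzchar(x)) {
    return(as.POSIXct(NA, tz = "UTC"))
  }
  # v1.1 dates carry English month/day abbreviations; force the C locale
  t <- withr::with_locale(c(LC_TIME = "C"), {
    suppressWarnings(as.POSIXct(x, format = TWITTER_V1_TIME, tz = "UTC"))
  })
  if (is.na(t)) {
    t <- suppressWarnings(as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  }
  if (is.na(t)) {
    t <- tryCatch(suppressWarnings(as.POSIXct(x, tz = "UTC")),
                  error = function(e) as.POSIXct(NA, tz = "UTC"))
  }
  t
}

chr_or <- function(x, default = "") {
  if (is.null(x) || length(x) == 0 || is.na(x)) default else as.character(x)
}

sniff_dialect <- function(raw) {
  keys <- names(raw)
  if ("user" %in% keys) return("v1")
  if ("tweet_id" %in% keys) return("normalized")
  "v2"
}

#' Normalize a raw tweet object into a flat record
#'
#' Accepts a parsed JSON object in the Twitter API v1.1 dialect (nested
#' `user` and `retweeted_status` sub-objects, `full_text` preferred over the
#' truncated `text`), a flattened v2-style dialect (`author_id`,
#' `referenced_tweets`), or this package's own normalized output. The
#' `auto` dialect sniffs by key presence.
#'
#' A record is flagged as a retweet when it carries a retweet sub-record
#' *or* its text begins with the `"RT @user:"` prefix convention.
#'
#' @param raw A parsed JSON object (a named list).
#' @param dialect One of `"auto"`, `"v1"`, `"v2"`, `"normalized"`.
#' @return A one-row tibble with columns `tweet_id`, `text`, `created_at`
#'   (POSIXct UTC), `user_id`, `user_name`, `user_description`,
#'   `user_location`, `place_country`, `place_full_name`, `place_type`,
#'   `is_retweet`, `is_quote`.
#' @examples
#' raw <- list(id_str = "1", text = "hello", created_at = "Wed Sep 02 10:00:00 +0000 2020",
#'             user = list(id_str = "u1", name = "A", description = "", location = ""))
#' normalize_record(raw)
#' @export
normalize_record <- function(raw, dialect = c("auto", "v1", "v2", "normalized")) {
  dialect <- match.arg(dialect)
  if (!is.list(raw)) {
    abort("`raw` must be a parsed JSON object (a named list).",
          class = "selfreportr_malformed_record")
  }
  if (dialect == "auto") dialect <- sniff_dialect(raw)

  if (dialect == "v1") {
    tweet_id <- chr_or(raw$id_str, chr_or(raw$id, NA_character_))
    user <- raw$user
    user_id <- if (is.list(user)) chr_or(user$id_str, chr_or(user$id, NA_character_)) else NA_character_
    text <- chr_or(raw$extended_tweet$full_text, chr_or(raw$full_text, chr_or(raw$text)))
    user_name <- chr_or(user$name)
    user_description <- chr_or(user$description)
    user_location <- chr_or(user$location)
    created_raw <- raw$created_at
    is_retweet <- !is.null(raw$retweeted_status)
    is_quote <- isTRUE(raw$is_quote_status)
    place <- raw$place
  } else if (dialect == "v2") {
    tweet_id <- chr_or(raw$id, NA_character_)
    user_id <- chr_or(raw$author_id, chr_or(raw$author$id, NA_character_))
    text <- chr_or(raw$text)
    user_name <- chr_or(raw$author_name, chr_or(raw$author$name))
    user_description <- chr_or(raw$author_description, chr_or(raw$author$description))
    user_location <- chr_or(raw$author_location, chr_or(raw$author$location))
    created_raw <- raw$created_at
    ref_types <- vapply(raw$referenced_tweets, function(r) chr_or(r$type), character(1))
    is_retweet <- "retweeted" %in% ref_types
    is_quote <- "quoted" %in% ref_types
    place <- raw$place
  } else { # normalized
    tweet_id <- chr_or(raw$tweet_id, NA_character_)
    user_id <- chr_or(raw$user_id, NA_character_)
    text <- chr_or(raw$text)
    user_name <- chr_or(raw$user_name)
    user_description <- chr_or(raw$user_description)
    user_location <- chr_or(raw$user_location)
    created_raw <- raw$created_at
    is_retweet <- isTRUE(raw$is_retweet)
    is_quote <- isTRUE(raw$is_quote)
    place <- list(country_code = raw$place_country, full_name = raw$place_full_name,
                  place_type = raw$place_type)
  }

  if (is.na(tweet_id) || !nzchar(tweet_id)) {
    abort("Malformed record: missing tweet identifier (key `id_str`/`id`/`tweet_id`).",
          class = "selfreportr_malformed_record")
  }
  if (is.na(user_id) || !nzchar(user_id)) {
    abort("Malformed record: missing author identifier (key `user.id_str`/`author_id`/`user_id`).",
          class = "selfreportr_malformed_record")
  }

  created_at <- parse_created_at(created_raw)
  if (is.na(created_at)) {
    warn(paste0("Record ", tweet_id, ": unparseable timestamp; using sentinel."),
         class = "selfreportr_sentinel_timestamp")
    created_at <- sentinel_time()
  }

  if (!is_retweet && stringr::str_detect(text, "^RT @\\w+")) {
    is_retweet <- TRUE
  }

  tibble::tibble(
    tweet_id = tweet_id,
    text = text,
    created_at = created_at,
    user_id = user_id,
    user_name = user_name,
    user_description = user_description,
    user_location = user_location,
    place_country = chr_or(place$country_code, NA_character_),
    place_full_name = chr_or(place$full_name, NA_character_),
    place_type = chr_or(place$place_type, NA_character_),
    is_retweet = is_retweet,
    is_quote = is_quote
  )
}

#' Read a JSON Lines tweet stream
#'
#' Reads one JSON object per line and normalizes each with
#' [normalize_record()]. Malformed lines are skipped and counted in a read
#' report attached as the `"read_report"` attribute (see [read_report()]);
#' they are never silently dropped. If more than half the non-empty lines
#' are malformed a format error is raised suggesting the wrong dialect was
#' chosen.
#'
#' @param path Path to a UTF-8 JSON Lines file.
#' @param dialect Passed to [normalize_record()].
#' @return A tibble of normalized records in file order, with a
#'   `read_report` attribute.
#' @export
read_tweet_stream <- function(path, dialect = "auto") {
  if (!file.exists(path)) {
    abort(paste0("Cannot read tweet stream: no such file: ", path),
          class = "selfreportr_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_lines <- length(lines)
  records <- vector("list", n_lines)
  skipped <- 0L
  for (i in seq_len(n_lines)) {
    rec <- tryCatch({
      raw <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
      normalize_record(raw, dialect)
    }, error = function(e) NULL)
    if (is.null(rec)) skipped <- skipped + 1L else records[[i]] <- rec
  }
  if (n_lines > 0 && skipped > n_lines / 2) {
    abort(paste0("More than half the lines (", skipped, "/", n_lines,
                 ") are malformed; is `dialect = \"", dialect, "\"` correct?"),
          class = "selfreportr_format_error")
  }
  out <- dplyr::bind_rows(records)
  if (nrow(out) == 0) out <- empty_records()
  attr(out, "read_report") <- tibble::tibble(
    n_lines = n_lines, n_records = n_lines - skipped, n_skipped = skipped
  )
  out
}

empty_records <- function() {
  tibble::tibble(
    tweet_id = character(), text = character(),
    created_at = as.POSIXct(character(), tz = "UTC"),
    user_id = character(), user_name = character(),
    user_description = character(), user_location = character(),
    place_country = character(), place_full_name = character(),
    place_type = character(), is_retweet = logical(), is_quote = logical()
  )
}

#' Read report of the last stream ingestion
#'
#' @param records A tibble returned by [read_tweet_stream()].
#' @return A one-row tibble with `n_lines`, `n_records`, `n_skipped`.
#' @export
read_report <- function(records) {
  rep <- attr(records, "read_report", exact = TRUE)
  if (is.null(rep)) {
    rep <- tibble::tibble(n_lines = NA_integer_, n_records = nrow(records),
                          n_skipped = NA_integer_)
  }
  rep
}

#' Write normalized records to JSON Lines
#'
#' Writes the package's normalized schema (one object per line, ISO-8601
#' timestamps). Re-reading with [read_tweet_stream()] round-trips to
#' field-identical records.
#'
#' @param records A tibble of normalized records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tweet_stream <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- as.list(records[i, ])
    r$created_at <- format(r$created_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    r <- r[!vapply(r, function(v) is.na(v) || identical(v, ""), logical(1)) |
             names(r) %in% c("text", "user_name", "user_description",
                             "user_location", "is_retweet", "is_quote")]
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Consolidate a stream into one profile record per user
#'
#' Profile fields are taken from each user's most recent record; ties on
#' `created_at` are broken by the lexicographically larger `tweet_id`
#' (deterministic and dialect-independent).
#'
#' @param records A tibble of normalized records.
#' @return A tibble with one row per distinct `user_id`: profile fields,
#'   place metadata of the chosen record, and `latest_seen` (the maximum
#'   `created_at` for that user).
#' @export
consolidate_users <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(
      user_id = character(), user_name = character(),
      user_description = character(), user_location = character(),
      place_country = character(), place_full_name = character(),
      place_type = character(),
      latest_seen = as.POSIXct(character(), tz = "UTC")
    ))
  }
  records |>
    dplyr::arrange(.data$user_id, .data$created_at, .data$tweet_id) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::transmute(
      user_id = .data$user_id,
      user_name = .data$user_name,
      user_description = .data$user_description,
      user_location = .data$user_location,
      place_country = .data$place_country,
      place_full_name = .data$place_full_name,
      place_type = .data$place_type,
      latest_seen = .data$created_at
    )
}
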