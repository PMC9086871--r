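# End-to-end orchestration: filter -> match -> deduplicate -> geolocate ->
# age -> cohort table.

#' Run the full identification pipeline on a record stream
#'
#' Stages, in order: retweet removal ([filter_stream()]); per-user profile
#' consolidation over the full stream ([consolidate_users()]); leftmost
#' self-report matching on retained tweet text with span-conditional
#' reported-speech exclusion, and on profile metadata
#' ([classify_user()] semantics, vectorized); deduplication across the
#' tweet and profile channels ([build_cohort()]); geolocation of cohort
#' users ([resolve_location()]); age resolution from cohort users' tweets
#' ([extract_age_mentions()], most recent mention, >= 13).
#'
#' @param records Tibble of normalized records (see [read_tweet_stream()]
#'   or [generate_corpus()]).
#' @param patterns A `pattern_set` (default: the shipped grammar).
#' @param gazetteer A `gazetteer` (default: the shipped one).
#' @param rs An [rs_config()].
#' @param age_cfg An [age_config()].
#' @param mode `"default"` (the measured operating point) or `"strict"`
#'   (adds third-person and trans/nonbinary exclusions).
#' @return A list of class `pipeline_result`: `cohort` (tibble `user_id`,
#'   `evidence`, `source_tweet_id`, `state`, `county`, `geo_source`,
#'   `age`, `age_group`), `users` (consolidated profiles), `decisions`
#'   (retweet filter decisions), and counts `n_records`, `n_retained`.
#' @export
run_pipeline <- function(records, patterns = NULL, gazetteer = NULL,
                         rs = rs_config(), age_cfg = age_config(),
                         mode = c("default", "strict")) {
  mode <- match.arg(mode)
  ps <- patterns %||% compile_pattern_set()
  g <- gazetteer %||% default_gazetteer()

  fl <- filter_stream(records)
  retained <- fl$retained
  users <- consolidate_users(records)

  # tweet channel: vectorized leftmost match, then the span rule
  tweet_users <- character(0)
  provenance <- tibble::tibble(user_id = character(),
                               source_tweet_id = character())
  if (nrow(retained) > 0) {
    m <- match_texts(retained$text, ps, "tweet", mode)
    hit <- which(!is.na(m$start))
    if (length(hit) > 0) {
      keep <- vapply(hit, function(i) {
        !detect_reported_speech(retained$text[i],
                                c(m$start[i], m$end[i]), rs)$reported
      }, logical(1))
      hit <- hit[keep]
    }
    if (length(hit) > 0) {
      hits <- retained[hit, c("user_id", "tweet_id", "created_at")]
      provenance <- hits |>
        dplyr::arrange(.data$created_at, .data$tweet_id) |>
        dplyr::distinct(.data$user_id, .keep_all = TRUE) |>
        dplyr::transmute(user_id = .data$user_id,
                         source_tweet_id = .data$tweet_id)
      tweet_users <- provenance$user_id
    }
  }

  # profile channel: description first, then display name
  profile_users <- character(0)
  if (nrow(users) > 0) {
    md <- match_texts(users$user_description, ps, "profile", mode)
    mn <- match_texts(users$user_name, ps, "profile", mode)
    hit_p <- !is.na(md$start) | !is.na(mn$start)
    if (mode == "strict") {
      hit_p <- hit_p & !stringr::str_detect(
        paste(users$user_description, users$user_name), TRANSNB_RE)
    }
    profile_users <- users$user_id[hit_p]
  }

  cohort <- build_cohort(tweet_users, profile_users)
  cohort <- dplyr::left_join(cohort, provenance, by = "user_id")

  geo <- geolocate_users(users[users$user_id %in% cohort$user_id, ], g)
  cohort <- dplyr::left_join(
    cohort,
    dplyr::rename(geo, geo_source = "source"),
    by = "user_id"
  )

  ages <- extract_user_ages(
    retained[retained$user_id %in% cohort$user_id, , drop = FALSE], age_cfg)
  cohort <- dplyr::left_join(
    cohort, ages[, c("user_id", "age", "age_group")], by = "user_id")

  structure(
    list(cohort = cohort, users = users, decisions = fl$decisions,
         n_records = nrow(records), n_retained = nrow(retained)),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  records:", x$n_records, "(", x$n_records - x$n_retained,
      "retweets dropped )\n")
  cat("  cohort:", nrow(x$cohort), "users —",
      sum(x$cohort$evidence == "tweet"), "tweet /",
      sum(x$cohort$evidence == "profile"), "profile /",
      sum(x$cohort$evidence == "both"), "both\n")
  cat("  state-resolved:", sum(!is.na(x$cohort$state)),
      "| county-resolved:", sum(!is.na(x$cohort$county)),
      "| aged:", sum(!is.na(x$cohort$age)), "\n")
  invisible(x)
}
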