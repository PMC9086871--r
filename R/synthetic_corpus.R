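# Seeded synthetic tweet-stream generator with ground truth. Each user is
# assigned one role: a genuine tweet or profile self-report, a
# third-person decoy, a trans/nonbinary profile decoy, retweet-only or
# quoted-speech-only noise, or background. Texts are filled from minimal
# paraphrase families around each role so that the generator and the
# pipeline are co-tested: genuine self-reports always match the default
# pattern set, retweets are always dropped, quoted self-reports are always
# flagged by the span rule.

ROLE_NAMES <- c("tp_tweet", "tp_profile", "fp_thirdperson", "fp_transnb",
                "retweet", "reported_speech", "background")

#' Synthetic corpus specification
#'
#' Defaults encode the stream conditions the pipeline targets: state-level
#' geolocation coverage 87.6%, county-level coverage 71.2% of those, age
#' coverage 47.6%, an age mix matching the observed cohort age
#' distribution, state weights skewed toward the eight highest-volume
#' states, and decoy rates set so the expected false-positive share is
#' 16.6% in the tweet channel and 14% in the profile channel (overall
#' expected precision about 0.85).
#'
#' @param n_users Number of users to simulate.
#' @param tp_tweet_rate,tp_profile_rate Fractions of users given a genuine
#'   first-person self-report tweet / profile.
#' @param fp_thirdperson_rate Fraction given a third-person identity
#'   mention (memorial-style decoy) that the default matcher still matches.
#' @param fp_transnb_rate Fraction given a transgender/nonbinary profile
#'   decoy that the default profile matcher still matches.
#' @param retweet_rate Fraction whose only identity content is a retweet
#'   of a self-report (must be removed by the noise filter).
#' @param reported_speech_rate Fraction whose only identity content is a
#'   quoted/attributed self-report (must be excluded by the span rule).
#' @param geo_coverage Fraction of users with a resolvable location.
#' @param county_coverage Fraction of geolocated users resolvable to a
#'   county (the rest carry a bare state name).
#' @param age_coverage Fraction of users who tweet their age.
#' @param state_weights Named categorical distribution over USPS codes.
#' @param age_distribution Named categorical distribution over the five
#'   age groups.
#' @param seed Integer seed; the same spec yields a byte-identical corpus.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_users = 2000,
                        tp_tweet_rate = 0.25,
                        tp_profile_rate = 0.16,
                        fp_thirdperson_rate = 0.0498,
                        fp_transnb_rate = 0.026,
                        retweet_rate = 0.10,
                        reported_speech_rate = 0.05,
                        geo_coverage = 0.876,
                        county_coverage = 0.712,
                        age_coverage = 0.476,
                        state_weights = default_state_weights(),
                        age_distribution = c("13-24" = 0.341, "25-34" = 0.344,
                                             "35-44" = 0.147, "45-54" = 0.094,
                                             "55+" = 0.074),
                        seed = 42L) {
  rates <- c(tp_tweet_rate, tp_profile_rate, fp_thirdperson_rate,
             fp_transnb_rate, retweet_rate, reported_speech_rate)
  stopifnot(n_users >= 1, all(rates >= 0), all(rates <= 1),
            sum(rates) <= 1,
            all(c(geo_coverage, county_coverage, age_coverage) >= 0),
            all(c(geo_coverage, county_coverage, age_coverage) <= 1))
  if (abs(sum(state_weights) - 1) > 1e-8) {
    state_weights <- state_weights / sum(state_weights)
  }
  if (!setequal(names(age_distribution), AGE_GROUPS)) {
    abort("`age_distribution` must be named by the five age groups.",
          class = "selfreportr_config_error")
  }
  age_distribution <- age_distribution / sum(age_distribution)
  structure(
    list(n_users = n_users, tp_tweet_rate = tp_tweet_rate,
         tp_profile_rate = tp_profile_rate,
         fp_thirdperson_rate = fp_thirdperson_rate,
         fp_transnb_rate = fp_transnb_rate,
         retweet_rate = retweet_rate,
         reported_speech_rate = reported_speech_rate,
         geo_coverage = geo_coverage, county_coverage = county_coverage,
         age_coverage = age_coverage, state_weights = state_weights,
         age_distribution = age_distribution, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

#' Default state weights for the synthetic corpus
#'
#' Skewed toward the eight states where the most users are observed
#' (CA, NY, TX, FL, IL, PA, OH, GA); the remaining states and DC share
#' the rest uniformly.
#'
#' @return Named numeric vector over 51 USPS codes summing to 1.
#' @export
default_state_weights <- function() {
  g <- default_gazetteer()
  big8 <- c(CA = 0.13, NY = 0.11, TX = 0.09, FL = 0.08, IL = 0.05,
            PA = 0.045, OH = 0.04, GA = 0.04)
  rest <- setdiff(g$states$usps, names(big8))
  w <- c(big8, setNames(rep((1 - sum(big8)) / length(rest), length(rest)), rest))
  w[order(names(w))]
}

#' Expected precision of the generator's role mixture
#'
#' The analytic value the pipeline's measured precision converges to on a
#' large corpus: TP roles over matched roles,
#' `(tp_tweet + tp_profile) / (tp_tweet + tp_profile + fp_thirdperson +
#' fp_transnb)`.
#'
#' @param spec A [corpus_spec()].
#' @return A fraction in \[0, 1\].
#' @export
analytic_precision <- function(spec) {
  tp <- spec$tp_tweet_rate + spec$tp_profile_rate
  fp <- spec$fp_thirdperson_rate + spec$fp_transnb_rate
  tp / (tp + fp)
}

ordinal_suffix <- function(n) {
  ifelse(n %% 100 %in% 11:13, "th",
         c("st", "nd", "rd", rep("th", 7))[pmin((n - 1) %% 10 + 1, 10)])
}

fill_one_of <- function(templates, n, ...) {
  idx <- sample(length(templates), n, replace = TRUE)
  args <- list(...)
  out <- character(n)
  for (i in seq_len(n)) {
    vals <- vapply(args, function(a) a[[i]], character(1))
    out[i] <- do.call(sprintf, c(list(templates[idx[i]]), as.list(vals)))
  }
  out
}

# text pools ---------------------------------------------------------------

# the fourth family uses a plural person term ("gay men like me")
SELFREPORT_TWEETS <- c(
  "I'm a %s %s and I'm not hiding it anymore.",
  "As a %s %s, I think our community deserves better.",
  "Being a %s %s in this city is wild sometimes.",
  "Honestly, %s %s like me just want a quiet weekend."
)
PLURAL_PERSON <- c(man = "men", guy = "guys", dude = "dudes")
THIRDPERSON_TWEETS <- c(
  "We will never forget his courage as a %s %s who spoke up.",
  "Celebrating his journey as a %s %s tonight.",
  "Remembering their colleague as a %s %s who inspired everyone."
)
REPORTED_SPEECH_TWEETS <- c(
  "\"I am a %s %s and I vote,\" he said.",
  "\"As a %s %s I disagree,\" the host said.",
  "The interview ended with: \"being a %s %s here is hard.\""
)
RETWEET_TWEETS <- c(
  "RT @voices: I'm a %s %s and I'm not hiding it anymore.",
  "RT @community: As a %s %s, I think our community deserves better."
)
TP_PROFILES <- c(
  "Proud %s %s. Coffee, film, and a very good dog.",
  "Just a %s %s from the midwest.",
  "Black %s %s, music lover.",
  "%s %s. Runner. Plant dad."
)
TRANSNB_PROFILES <- c(
  "Proud %s trans %s. Films, food, long walks. He/him OR they/them.",
  "%s nonbinary %s figuring it out. They/them.",
  "50+ %s trans %s, writer, film and food lover."
)
NEUTRAL_PROFILES <- c(
  "Sports. Music. Opinions my own.", "Part-time dreamer.",
  "Taco enthusiast.", "Midwest born and raised.", "Here for the memes.",
  ""
)
BACKGROUND_TWEETS <- c(
  "Coffee first, everything else later.",
  "That sunset tonight was something else.",
  "New playlist on repeat all week.",
  "Traffic ruined my whole mood today.",
  "Weekend plans: absolutely nothing.",
  "Leftover pizza is the best breakfast.",
  "Rainy days are for old movies.",
  "Finally cleaned the apartment.",
  "The gym was packed again."
)
AGE_TWEETS <- c(
  "I'm %d and honestly thriving.",
  "Turned %d today, cake was mandatory.",
  "My %d%s birthday party got rained out."
)
UNRESOLVABLE_LOCATIONS <- c("", "Earth", "somewhere over the rainbow",
                            "\U0001F308\U0001F30D", "Mars")

sample_identity <- function(n) sample(c("gay", "bi", "bisexual"), n, replace = TRUE)
sample_person <- function(n) sample(c("man", "guy", "dude"), n, replace = TRUE)

age_value_for_group <- function(groups) {
  lo <- c("13-24" = 13, "25-34" = 25, "35-44" = 35, "45-54" = 45, "55+" = 55)
  hi <- c("13-24" = 24, "25-34" = 34, "35-44" = 44, "45-54" = 54, "55+" = 75)
  vapply(groups, function(gr) {
    as.integer(sample(seq(lo[[gr]], hi[[gr]]), 1))
  }, integer(1))
}

#' Generate a labeled synthetic tweet corpus
#'
#' Deterministic under the spec's seed (identical records and truth,
#' byte-identical files via [write_corpus()]).
#'
#' @param spec A [corpus_spec()].
#' @param gazetteer Gazetteer used for location strings (default the
#'   shipped one).
#' @return A list of class `synthetic_corpus` with `records` (normalized
#'   record tibble), `truth` (tibble `user_id`, `is_true_positive`,
#'   `channel`, `role`, `state`, `county`, `age`), and `spec`.
#' @export
generate_corpus <- function(spec = corpus_spec(), gazetteer = default_gazetteer()) {
  withr::with_seed(spec$seed, generate_corpus_impl(spec, gazetteer))
}

generate_corpus_impl <- function(spec, g) {
  n <- spec$n_users
  user_id <- sprintf("u%06d", seq_len(n))
  probs <- c(spec$tp_tweet_rate, spec$tp_profile_rate, spec$fp_thirdperson_rate,
             spec$fp_transnb_rate, spec$retweet_rate, spec$reported_speech_rate)
  probs <- c(probs, 1 - sum(probs))
  role <- sample(ROLE_NAMES, n, replace = TRUE, prob = probs)

  state <- sample(names(spec$state_weights), n, replace = TRUE,
                  prob = spec$state_weights)
  has_state <- runif(n) < spec$geo_coverage
  has_county <- has_state & runif(n) < spec$county_coverage

  # location strings
  state_names <- setNames(g$states$name, g$states$usps)
  cities_by_state <- split(g$cities, g$cities$state)
  location <- character(n)
  county <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (has_county[i]) {
      cs <- cities_by_state[[state[i]]]
      if (is.null(cs) || nrow(cs) == 0) { # DC has no city entry
        location[i] <- "Washington DC"
        county[i] <- "District of Columbia"
      } else {
        j <- sample(nrow(cs), 1)
        location[i] <- paste0(cs$city[j], ", ", cs$state[j])
        county[i] <- cs$county[j]
      }
    } else if (has_state[i]) {
      location[i] <- state_names[[state[i]]]
    } else {
      location[i] <- sample(UNRESOLVABLE_LOCATIONS, 1)
    }
  }

  has_age <- runif(n) < spec$age_coverage
  age_grp <- sample(names(spec$age_distribution), n, replace = TRUE,
                    prob = spec$age_distribution)
  age <- ifelse(has_age, age_value_for_group(age_grp), NA_integer_)

  # profiles by role
  description <- character(n)
  for (r in ROLE_NAMES) {
    idx <- which(role == r)
    if (length(idx) == 0) next
    description[idx] <- switch(
      r,
      tp_profile = fill_one_of(TP_PROFILES, length(idx),
                               sample_identity(length(idx)),
                               sample_person(length(idx))),
      fp_transnb = fill_one_of(TRANSNB_PROFILES, length(idx),
                               sample_identity(length(idx)),
                               sample_person(length(idx))),
      sample(NEUTRAL_PROFILES, length(idx), replace = TRUE)
    )
  }
  user_name <- paste0("user_", seq_len(n))

  # tweets: background for everyone, plus one role tweet, plus one age tweet
  n_bg <- 1 + rpois(n, 0.6)
  bg_user <- rep(seq_len(n), n_bg)
  bg_text <- sample(BACKGROUND_TWEETS, length(bg_user), replace = TRUE)
  bg_rt <- rep(FALSE, length(bg_user))

  role_idx <- which(role %in% c("tp_tweet", "fp_thirdperson", "retweet",
                                "reported_speech"))
  role_text <- character(length(role_idx))
  for (r in c("tp_tweet", "fp_thirdperson", "retweet", "reported_speech")) {
    sel <- which(role[role_idx] == r)
    if (length(sel) == 0) next
    pool <- switch(r,
                   tp_tweet = SELFREPORT_TWEETS,
                   fp_thirdperson = THIRDPERSON_TWEETS,
                   retweet = RETWEET_TWEETS,
                   reported_speech = REPORTED_SPEECH_TWEETS)
    if (r == "tp_tweet") {
      idx <- sample(length(pool), length(sel), replace = TRUE)
      ident <- sample_identity(length(sel))
      pers <- sample_person(length(sel))
      pers <- ifelse(idx == 4, PLURAL_PERSON[pers], pers)
      role_text[sel] <- sprintf(pool[idx], ident, pers)
    } else {
      role_text[sel] <- fill_one_of(pool, length(sel),
                                    sample_identity(length(sel)),
                                    sample_person(length(sel)))
    }
  }
  role_rt <- role[role_idx] == "retweet"

  age_idx <- which(has_age)
  age_text <- character(length(age_idx))
  if (length(age_idx) > 0) {
    tmpl <- sample(length(AGE_TWEETS), length(age_idx), replace = TRUE)
    for (i in seq_along(age_idx)) {
      v <- age[age_idx[i]]
      age_text[i] <- if (tmpl[i] == 3) {
        sprintf(AGE_TWEETS[3], v, ordinal_suffix(v))
      } else {
        sprintf(AGE_TWEETS[tmpl[i]], v)
      }
    }
  }

  u <- c(bg_user, role_idx, age_idx)
  text <- c(bg_text, role_text, age_text)
  rt <- c(bg_rt, role_rt, rep(FALSE, length(age_idx)))
  n_tweets <- length(u)

  base <- as.POSIXct("2020-09-01 00:00:00", tz = "UTC")
  created_at <- base + round(runif(n_tweets, 0, 120 * 86400))
  ord <- order(u, created_at)
  u <- u[ord]; text <- text[ord]; rt <- rt[ord]; created_at <- created_at[ord]

  records <- tibble::tibble(
    tweet_id = sprintf("t%08d", seq_len(n_tweets)),
    text = text,
    created_at = created_at,
    user_id = user_id[u],
    user_name = user_name[u],
    user_description = description[u],
    user_location = location[u],
    place_country = NA_character_,
    place_full_name = NA_character_,
    place_type = NA_character_,
    is_retweet = rt,
    is_quote = FALSE
  )

  truth <- tibble::tibble(
    user_id = user_id,
    is_true_positive = role %in% c("tp_tweet", "tp_profile"),
    channel = dplyr::case_when(role == "tp_tweet" ~ "tweet",
                               role == "tp_profile" ~ "profile",
                               TRUE ~ "none"),
    role = role,
    state = ifelse(has_state, state, NA_character_),
    county = county,
    age = age
  )

  structure(list(records = records, truth = truth, spec = spec),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$truth), " users, ", nrow(x$records),
      " records (seed ", x$spec$seed, ")\n", sep = "")
  print(table(x$truth$role))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits the tweet stream as JSON Lines — by default in the v1.1 dialect
#' (nested `user` object, `retweeted_status` marker) — and the ground
#' truth as CSV.
#'
#' @param corpus A `synthetic_corpus`.
#' @param corpus_path,truth_path Output paths (`truth_path` optional).
#' @param dialect `"v1"` or `"normalized"`.
#' @return `corpus_path`, invisibly.
#' @export
write_corpus <- function(corpus, corpus_path, truth_path = NULL,
                         dialect = c("v1", "normalized")) {
  dialect <- match.arg(dialect)
  r <- corpus$records
  if (dialect == "normalized") {
    write_tweet_stream(r, corpus_path)
  } else {
    lines <- vapply(seq_len(nrow(r)), function(i) {
      obj <- list(
        created_at = withr::with_locale(
          c(LC_TIME = "C"),
          format(r$created_at[i], "%a %b %d %H:%M:%S +0000 %Y", tz = "UTC")),
        id_str = r$tweet_id[i],
        full_text = r$text[i],
        user = list(id_str = r$user_id[i], name = r$user_name[i],
                    description = r$user_description[i],
                    location = r$user_location[i]),
        is_quote_status = r$is_quote[i]
      )
      if (r$is_retweet[i]) obj$retweeted_status <- list(id_str = paste0("o", i))
      as.character(jsonlite::toJSON(obj, auto_unbox = TRUE))
    }, character(1))
    writeLines(lines, corpus_path, useBytes = TRUE)
  }
  if (!is.null(truth_path)) readr::write_csv(corpus$truth, truth_path)
  invisible(corpus_path)
}

#' Score a pipeline cohort against synthetic ground truth
#'
#' Extends the precision-only live evaluation to synthetic data where the
#' truth is known: precision over matched users, recall over true-positive
#' users, and exact-match accuracy of resolved state, county, and age
#' among true-positive cohort users whose truth value is known.
#'
#' @param cohort Cohort tibble (from [run_pipeline()]) with `user_id` and
#'   optionally `state`, `county`, `age`.
#' @param truth Ground-truth tibble from [generate_corpus()].
#' @return A list of class `pipeline_score`: `precision`, `recall`,
#'   `state_accuracy`, `county_accuracy`, `age_accuracy`, `n_cohort`,
#'   `n_true`. Precision is `NA` (absent) for an empty cohort.
#' @export
score_pipeline <- function(cohort, truth) {
  unknown <- setdiff(cohort$user_id, truth$user_id)
  if (length(unknown) > 0) {
    abort(paste0("Cohort users absent from truth: ",
                 paste(head(unknown, 5), collapse = ", ")),
          class = "selfreportr_contract_error")
  }
  idx <- match(cohort$user_id, truth$user_id)
  is_tp <- truth$is_true_positive[idx]
  n_true <- sum(truth$is_true_positive)
  precision <- if (nrow(cohort) == 0) NA_real_ else mean(is_tp)
  recall <- if (n_true == 0) NA_real_ else sum(is_tp) / n_true

  acc <- function(pred, true, mask) {
    m <- mask & !is.na(true)
    if (!any(m)) return(NA_real_)
    mean(!is.na(pred[m]) & pred[m] == true[m])
  }
  has_geo <- "state" %in% names(cohort)
  has_age <- "age" %in% names(cohort)
  structure(
    list(
      precision = precision,
      recall = recall,
      state_accuracy = if (has_geo) acc(cohort$state, truth$state[idx], is_tp) else NA_real_,
      county_accuracy = if (has_geo) acc(cohort$county, truth$county[idx], is_tp) else NA_real_,
      age_accuracy = if (has_age) acc(cohort$age, truth$age[idx], is_tp) else NA_real_,
      n_cohort = nrow(cohort),
      n_true = n_true
    ),
    class = "pipeline_score"
  )
}

#' @export
print.pipeline_score <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", formatC(v, digits = 3, format = "f"))
  cat("<pipeline_score> cohort ", x$n_cohort, " / true ", x$n_true, "\n", sep = "")
  cat("  precision ", fmt(x$precision), "  recall ", fmt(x$recall), "\n", sep = "")
  cat("  accuracy: state ", fmt(x$state_accuracy), "  county ",
      fmt(x$county_accuracy), "  age ", fmt(x$age_accuracy), "\n", sep = "")
  invisible(x)
}
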