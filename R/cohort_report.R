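# Cohort deduplication and demographic reporting: percentage arithmetic
# with half-up rounding, county/age tables, jurisdiction overlaps.

#' Deduplicate matched users into a cohort
#'
#' Set union of the tweet- and profile-matched user sets; users in both
#' get evidence `"both"` and are counted once.
#'
#' @param tweet_matched,profile_matched Character vectors of user ids (or
#'   tibbles with a `user_id` column).
#' @return Tibble `user_id`, `evidence`.
#' @examples
#' build_cohort(c("A", "B"), c("B", "C"))
#' @export
build_cohort <- function(tweet_matched, profile_matched) {
  as_ids <- function(x) {
    if (is.data.frame(x)) unique(x$user_id) else unique(as.character(x))
  }
  tw <- as_ids(tweet_matched)
  pr <- as_ids(profile_matched)
  ids <- union(tw, pr)
  tibble::tibble(
    user_id = ids,
    evidence = dplyr::case_when(
      ids %in% tw & ids %in% pr ~ "both",
      ids %in% tw ~ "tweet",
      TRUE ~ "profile"
    )
  )
}

#' Percentage with half-up rounding
#'
#' Computes `100 * numerator / denominator` rounded half-up (not banker's)
#' to `decimals` places, using exact integer arithmetic so that terminating
#' decimals and exact ties round the way published tables do (e.g.
#' `pct(417, 500, 1)` is 83.4, `pct(430, 500, 0)` is 86).
#'
#' @param numerator,denominator Whole-number counts, `0 <= numerator <=
#'   denominator`, `denominator > 0`. Vectorized.
#' @param decimals Non-negative integer number of decimal places.
#' @return Numeric percentage(s).
#' @export
pct <- function(numerator, denominator, decimals = 1) {
  if (any(is.na(numerator)) || any(is.na(denominator)) ||
      any(numerator != floor(numerator)) || any(denominator != floor(denominator))) {
    abort("`numerator` and `denominator` must be whole numbers.",
          class = "selfreportr_contract_error")
  }
  if (any(denominator <= 0)) {
    abort("`denominator` must be positive.", class = "selfreportr_contract_error")
  }
  if (any(numerator < 0) || any(numerator > denominator)) {
    abort("`numerator` must lie in [0, denominator].",
          class = "selfreportr_contract_error")
  }
  stopifnot(length(decimals) == 1, decimals >= 0, decimals == floor(decimals))
  scale <- 10^decimals
  # half-up on the exact rational 100*num/den:
  # floor((100*num*scale + den/2) / den) done in integer arithmetic
  (200 * numerator * scale + denominator) %/% (2 * denominator) / scale
}

#' Round half-up (decimal places)
#'
#' Companion to [pct()] for non-ratio quantities (means, precision):
#' standard half-up decimal rounding of a numeric value.
#'
#' @param x Numeric vector.
#' @param decimals Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, decimals = 1) {
  scale <- 10^decimals
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' State-level counts of a geolocated cohort
#'
#' @param cohort Cohort tibble with a `state` column.
#' @return Tibble `state`, `n`, `share_pct` (share of state-resolved
#'   users, half-up to 1 decimal), sorted by descending count.
#' @export
state_table <- function(cohort) {
  resolved <- cohort[!is.na(cohort$state), , drop = FALSE]
  if (nrow(resolved) == 0) {
    return(tibble::tibble(state = character(), n = integer(),
                          share_pct = numeric()))
  }
  resolved |>
    dplyr::count(.data$state, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$state) |>
    dplyr::mutate(share_pct = pct(.data$n, nrow(resolved), 1))
}

#' County table of a geolocated cohort
#'
#' Counts per (county, state) among county-resolved users; rows with at
#' least `min_count` users, sorted by descending count. Shares use the
#' number of county-resolved users as denominator, not the cohort size.
#'
#' @param cohort Cohort tibble with `county` and `state` columns.
#' @param min_count Minimum user count for a row to appear (default 100).
#' @return Tibble `county`, `state`, `n`, `share_pct`.
#' @export
county_table <- function(cohort, min_count = 100) {
  resolved <- cohort[!is.na(cohort$county), , drop = FALSE]
  if (nrow(resolved) == 0) {
    return(tibble::tibble(county = character(), state = character(),
                          n = integer(), share_pct = numeric()))
  }
  resolved |>
    dplyr::count(.data$county, .data$state, name = "n") |>
    dplyr::filter(.data$n >= min_count) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$county) |>
    dplyr::mutate(share_pct = pct(.data$n, nrow(resolved), 1))
}

#' Age distribution table
#'
#' Counts per age group over users with a resolved age; shares half-up to
#' 1 decimal over the aged-user denominator. All five groups are listed
#' even when empty. An empty denominator yields an empty table with a
#' warning rather than division by zero.
#'
#' @param cohort Cohort tibble with `age_group` column.
#' @return Tibble `age_group`, `n`, `share_pct`.
#' @export
age_table <- function(cohort) {
  aged <- cohort[!is.na(cohort$age_group), , drop = FALSE]
  if (nrow(aged) == 0) {
    warn("No users with a resolved age; age table is empty (denominator 0).")
    return(tibble::tibble(age_group = character(), n = integer(),
                          share_pct = numeric()))
  }
  counts <- table(factor(aged$age_group, levels = AGE_GROUPS))
  tibble::tibble(
    age_group = AGE_GROUPS,
    n = as.integer(counts),
    share_pct = pct(as.integer(counts), nrow(aged), 1)
  )
}

#' Summary statistics of resolved ages
#'
#' Mean and SD to 1 decimal (half-up), integer-valued median reported as
#' is.
#'
#' @param cohort Cohort tibble with an `age` column.
#' @return One-row tibble `n`, `mean`, `sd`, `median`.
#' @export
age_stats <- function(cohort) {
  ages <- cohort$age[!is.na(cohort$age)]
  tibble::tibble(
    n = length(ages),
    mean = round_half_up(mean(ages), 1),
    sd = round_half_up(sd(ages), 1),
    median = median(ages)
  )
}

#' Load a jurisdiction list
#'
#' Plain-text CSV with columns `kind` (`state`/`county`), `name`, `state`.
#' All entries are validated against the gazetteer when one is supplied.
#'
#' @param path CSV path.
#' @param name Display name for the list (defaults to the file stem).
#' @param gazetteer Optional `gazetteer` for referential validation.
#' @return A list of class `jurisdiction_list` with `name`, `states`
#'   (USPS codes), `counties` (tibble `county`, `state`).
#' @export
load_jurisdiction_list <- function(path, name = NULL, gazetteer = NULL) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  if (!all(c("kind", "name", "state") %in% names(raw))) {
    abort("Jurisdiction list must have columns kind, name, state.",
          class = "selfreportr_jurisdiction_error")
  }
  states <- raw$state[raw$kind == "state"]
  counties <- tibble::tibble(
    county = raw$name[raw$kind == "county"],
    state = raw$state[raw$kind == "county"]
  )
  if (length(states) + nrow(counties) == 0) {
    abort("Jurisdiction list is empty.", class = "selfreportr_jurisdiction_error")
  }
  if (!is.null(gazetteer)) {
    bad_s <- setdiff(states, gazetteer$states$usps)
    bad_c <- dplyr::anti_join(counties, gazetteer$counties,
                              by = c("county", "state"))
    if (length(bad_s) > 0 || nrow(bad_c) > 0) {
      abort(paste0("Jurisdiction list entries missing from gazetteer: ",
                   paste(c(bad_s, bad_c$county), collapse = ", ")),
            class = "selfreportr_jurisdiction_error")
    }
  }
  structure(
    list(name = name %||% sub("\\.[^.]*$", "", basename(path)),
         states = states, counties = counties),
    class = "jurisdiction_list"
  )
}

#' Shipped jurisdiction lists
#'
#' The top-10 new-HIV-diagnosis states and the Ending the HIV Epidemic
#' (EHE) Phase-1 priority jurisdictions, as editable plain-text fixtures.
#'
#' @return Named list of two `jurisdiction_list` objects: `top10_hiv_states`
#'   and `ehe`.
#' @export
default_jurisdiction_lists <- function() {
  dir <- system.file("extdata", "jurisdictions", package = "selfreportr")
  g <- default_gazetteer()
  list(
    top10_hiv_states = load_jurisdiction_list(
      file.path(dir, "top10_hiv_states.csv"),
      name = "Top 10 states by new HIV diagnoses", gazetteer = g),
    ehe = load_jurisdiction_list(
      file.path(dir, "ehe_jurisdictions.csv"),
      name = "EHE priority jurisdictions", gazetteer = g)
  )
}

#' Overlap of a geolocated cohort with a jurisdiction list
#'
#' A user counts toward the list when their resolved county is in the
#' list's counties *or* their resolved state is in the list's states. The
#' denominator is the number of state-resolved or county-resolved users,
#' per `denominator_rule`.
#'
#' @param cohort Cohort tibble with `state`, `county` columns.
#' @param jl A `jurisdiction_list`.
#' @param denominator_rule `"state_resolved"` or `"county_resolved"`.
#' @return One-row tibble `name`, `numerator`, `denominator`, `share_pct`.
#' @export
jurisdiction_overlap <- function(cohort, jl,
                                 denominator_rule = c("state_resolved",
                                                      "county_resolved")) {
  denominator_rule <- match.arg(denominator_rule)
  base <- if (denominator_rule == "state_resolved") {
    cohort[!is.na(cohort$state), , drop = FALSE]
  } else {
    cohort[!is.na(cohort$county), , drop = FALSE]
  }
  if (nrow(base) == 0) {
    abort("Empty denominator: no users resolved at the requested level.",
          class = "selfreportr_contract_error")
  }
  county_key <- paste(jl$counties$county, jl$counties$state)
  in_list <- (!is.na(base$county) & paste(base$county, base$state) %in% county_key) |
    (base$state %in% jl$states)
  tibble::tibble(
    name = jl$name,
    numerator = sum(in_list),
    denominator = nrow(base),
    share_pct = pct(sum(in_list), nrow(base), 1)
  )
}

#' Full demographic summary of a cohort
#'
#' @param cohort Cohort tibble with geolocation and age columns.
#' @param jurisdictions Named list of `jurisdiction_list` objects (default:
#'   the shipped lists); overlaps use the state-resolved denominator for
#'   state-based lists and county-resolved for county-based ones.
#' @param min_count Passed to [county_table()].
#' @return A list of class `demographic_summary`: `state_counts`,
#'   `county_table`, `age_table`, `age_stats`, `overlaps`, `denominators`.
#' @export
demographic_summary <- function(cohort,
                                jurisdictions = default_jurisdiction_lists(),
                                min_count = 100) {
  n_state <- sum(!is.na(cohort$state))
  n_county <- sum(!is.na(cohort$county))
  overlaps <- dplyr::bind_rows(lapply(jurisdictions, function(jl) {
    rule <- if (nrow(jl$counties) > 0) "county_resolved" else "state_resolved"
    jurisdiction_overlap(cohort, jl, rule)
  }))
  structure(
    list(
      state_counts = state_table(cohort),
      county_table = county_table(cohort, min_count),
      age_table = age_table(cohort),
      age_stats = age_stats(cohort),
      overlaps = overlaps,
      denominators = tibble::tibble(
        n_users = nrow(cohort), n_state_resolved = n_state,
        n_county_resolved = n_county,
        n_aged = sum(!is.na(cohort$age))
      )
    ),
    class = "demographic_summary"
  )
}

#' @export
print.demographic_summary <- function(x, ...) {
  d <- x$denominators
  cat("<demographic_summary>\n")
  cat("  users:", d$n_users,
      "| state-resolved:", d$n_state_resolved,
      "| county-resolved:", d$n_county_resolved,
      "| aged:", d$n_aged, "\n")
  cat("  top counties:\n")
  print(utils::head(x$county_table, 5))
  invisible(x)
}
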