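# Gazetteer-based resolution of free-text profile locations to US state
# and (where possible) county. Precision-first: ambiguous names without a
# state hint resolve to none rather than guessing.

#' Load a gazetteer from TSV
#'
#' The TSV must have columns `kind` (`state`/`county`/`city`/`alias`),
#' `name`, `state`, `county`. States define the USPS code space; counties
#' must reference a known state; cities map to a known (county, state);
#' aliases (informal names such as "nyc") point at an existing state or
#' (county, state) entry. Duplicate `(kind, name, state)` rows and dangling
#' references are rejected with the offending line number.
#'
#' @param path Path to the gazetteer TSV.
#' @return An object of class `gazetteer` with tibbles `states`,
#'   `counties`, `cities`, `aliases`.
#' @export
load_gazetteer <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         comment = "#", progress = FALSE)
  required <- c("kind", "name", "state", "county")
  if (!all(required %in% names(raw))) {
    abort(paste0("Gazetteer must have columns: ", paste(required, collapse = ", ")),
          class = "selfreportr_gazetteer_error")
  }
  # line numbers for error messages (1-based data rows; header not counted)
  raw$line <- seq_len(nrow(raw))
  bad_kind <- which(!raw$kind %in% c("state", "county", "city", "alias"))
  if (length(bad_kind) > 0) {
    abort(paste0("Gazetteer row ", bad_kind[1], ": unknown kind `",
                 raw$kind[bad_kind[1]], "`."),
          class = "selfreportr_gazetteer_error")
  }
  dup <- which(duplicated(raw[, c("kind", "name", "state")]))
  if (length(dup) > 0) {
    abort(paste0("Gazetteer row ", dup[1], ": duplicate (",
                 raw$kind[dup[1]], ", ", raw$name[dup[1]], ", ",
                 raw$state[dup[1]], ")."),
          class = "selfreportr_gazetteer_error")
  }

  states <- raw[raw$kind == "state", ]
  usps <- states$state
  check_state <- function(rows, what) {
    bad <- rows$line[!rows$state %in% usps]
    if (length(bad) > 0) {
      abort(paste0("Gazetteer row ", bad[1], ": ", what,
                   " references unknown state `",
                   raw$state[raw$line == bad[1]], "`."),
            class = "selfreportr_gazetteer_error")
    }
  }
  counties <- raw[raw$kind == "county", ]
  check_state(counties, "county")
  county_key <- paste(tolower(counties$name), counties$state)

  cities <- raw[raw$kind == "city", ]
  check_state(cities, "city")
  bad_city <- cities$line[!paste(tolower(cities$county), cities$state) %in% county_key]
  if (length(bad_city) > 0) {
    abort(paste0("Gazetteer row ", bad_city[1],
                 ": city references unknown county."),
          class = "selfreportr_gazetteer_error")
  }

  aliases <- raw[raw$kind == "alias", ]
  check_state(aliases, "alias")
  has_county <- !is.na(aliases$county) & nzchar(aliases$county)
  bad_alias <- aliases$line[has_county &
                              !paste(tolower(aliases$county), aliases$state) %in% county_key]
  if (length(bad_alias) > 0) {
    abort(paste0("Gazetteer row ", bad_alias[1],
                 ": alias references unknown county."),
          class = "selfreportr_gazetteer_error")
  }

  structure(
    list(
      states = tibble::tibble(name = states$name, usps = usps,
                              key = tolower(states$name)),
      counties = tibble::tibble(county = counties$name, state = counties$state,
                                key = tolower(counties$name)),
      cities = tibble::tibble(city = cities$name, state = cities$state,
                              county = cities$county, key = tolower(cities$name)),
      aliases = tibble::tibble(alias = tolower(aliases$name), state = aliases$state,
                               county = ifelse(has_county, aliases$county,
                                               NA_character_))
    ),
    class = "gazetteer"
  )
}

#' @export
print.gazetteer <- function(x, ...) {
  cat("<gazetteer> ", nrow(x$states), " states, ", nrow(x$counties),
      " counties, ", nrow(x$cities), " cities, ", nrow(x$aliases),
      " aliases\n", sep = "")
  invisible(x)
}

#' Shipped default gazetteer
#'
#' Loads (and caches) the gazetteer TSV shipped with the package: all 50
#' states plus DC, at least one county and city per state, the major
#' metropolitan counties, and informal aliases ("nyc", "philly", ...).
#' "nyc" maps to New York County (Manhattan); the five boroughs are
#' present individually.
#'
#' @return A `gazetteer`.
#' @export
default_gazetteer <- function() {
  if (is.null(.selfreportr_cache$gazetteer)) {
    .selfreportr_cache$gazetteer <- load_gazetteer(
      system.file("extdata", "gazetteer.tsv", package = "selfreportr")
    )
  }
  .selfreportr_cache$gazetteer
}

clean_tokens <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  if (!stringr::str_detect(text, "[A-Za-z]")) return(character(0)) # emoji / non-Latin
  toks <- stringr::str_split(text, "[,/|;•·]+")[[1]]
  toks <- stringr::str_trim(stringr::str_replace_all(toks, "[^A-Za-z. '’-]", " "))
  toks <- stringr::str_squish(toks)
  toks <- stringr::str_remove_all(toks, "\\.")
  tolower(toks[nzchar(toks)])
}

resolve_freetext <- function(text, g) {
  none <- list(state = NA_character_, county = NA_character_)
  toks <- clean_tokens(text)
  if (length(toks) == 0) return(none)

  # state hints from any token (full name or 2-letter USPS code)
  hint <- NA_character_
  for (tk in toks) {
    if (nchar(tk) == 2 && toupper(tk) %in% g$states$usps) {
      hint <- toupper(tk); break
    }
    i <- match(tk, g$states$key)
    if (!is.na(i)) { hint <- g$states$usps[i]; break }
  }

  # 1. aliases (whole-string first, e.g. "washington dc", then per token)
  for (tk in c(paste(toks, collapse = " "), toks)) {
    i <- match(tk, g$aliases$alias)
    if (!is.na(i)) {
      return(list(state = g$aliases$state[i], county = g$aliases$county[i]))
    }
  }
  # 2. cities -> (county, state); a token equal to a state name is treated
  #    as a state, and ambiguous city names need a state hint
  for (tk in toks) {
    if (tk %in% g$states$key) next
    hits <- which(g$cities$key == tk)
    if (length(hits) == 0) next
    if (length(hits) > 1) {
      hits <- hits[g$cities$state[hits] == hint]
      if (length(hits) != 1) next # ambiguous without (or despite) a hint
    } else if (!is.na(hint) && g$cities$state[hits] != hint) {
      next # hint contradicts the unique candidate; don't guess
    }
    return(list(state = g$cities$state[hits], county = g$cities$county[hits]))
  }
  # 3. counties (with or without the literal "county" suffix); a token
  #    equal to a state name is still treated as a state
  for (tk in toks) {
    if (tk %in% g$states$key) next
    for (cand in unique(c(tk, paste(tk, "county")))) {
      hits <- which(g$counties$key == cand)
      if (length(hits) == 0) next
      if (length(hits) > 1) {
        hits <- hits[g$counties$state[hits] == hint]
        if (length(hits) != 1) next
      } else if (!is.na(hint) && g$counties$state[hits] != hint) {
        next
      }
      return(list(state = g$counties$state[hits], county = g$counties$county[hits]))
    }
  }
  # 4. state only
  if (!is.na(hint)) return(list(state = hint, county = NA_character_))
  none
}

#' Resolve one user's location to US state and county
#'
#' Structured place metadata (when present and US) takes priority over the
#' free-text profile location. Free text is tokenized on commas/slashes and
#' matched case-insensitively against aliases, then cities (which yield a
#' county and state), then counties, then states. Non-US or unresolvable
#' input yields no resolution — a value, not an error.
#'
#' @param location Free-text profile location (may be `NA`/empty).
#' @param gazetteer A `gazetteer`.
#' @param place_country,place_full_name Optional structured place metadata
#'   (ISO country code and display name) from the tweet object.
#' @return A one-row tibble `state` (USPS or `NA`), `county` (canonical
#'   name or `NA`), `source` (`"place_metadata"`/`"profile_location"`/`NA`).
#' @examples
#' g <- default_gazetteer()
#' resolve_location("Los Angeles, CA", g)
#' resolve_location("Texas", g)
#' @export
resolve_location <- function(location, gazetteer = default_gazetteer(),
                             place_country = NA, place_full_name = NA) {
  if (!is.na(place_full_name) && identical(place_country, "US")) {
    r <- resolve_freetext(place_full_name, gazetteer)
    if (!is.na(r$state)) {
      return(tibble::tibble(state = r$state, county = r$county,
                            source = "place_metadata"))
    }
  }
  r <- resolve_freetext(location, gazetteer)
  tibble::tibble(
    state = r$state, county = r$county,
    source = ifelse(is.na(r$state), NA_character_, "profile_location")
  )
}

#' Geolocate a table of users
#'
#' Vectorized wrapper over [resolve_location()].
#'
#' @param users Tibble from [consolidate_users()].
#' @param gazetteer A `gazetteer`.
#' @return Tibble `user_id`, `state`, `county`, `source`.
#' @export
geolocate_users <- function(users, gazetteer = default_gazetteer()) {
  if (nrow(users) == 0) {
    return(tibble::tibble(user_id = character(), state = character(),
                          county = character(), source = character()))
  }
  res <- lapply(seq_len(nrow(users)), function(i) {
    resolve_location(users$user_location[i], gazetteer,
                     place_country = users$place_country[i] %||% NA,
                     place_full_name = users$place_full_name[i] %||% NA)
  })
  dplyr::bind_cols(tibble::tibble(user_id = users$user_id),
                   dplyr::bind_rows(res))
}
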