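# Fixture builders and independent oracles used across the suite.

make_rec <- function(tweet_id = "t1", text = "hello", user_id = "u1",
                     created_at = "2020-09-02 10:00:00",
                     user_name = "name", user_description = "",
                     user_location = "", is_retweet = FALSE,
                     is_quote = FALSE, place_country = NA_character_,
                     place_full_name = NA_character_) {
  tibble::tibble(
    tweet_id = tweet_id, text = text,
    created_at = as.POSIXct(created_at, tz = "UTC"),
    user_id = user_id, user_name = user_name,
    user_description = user_description, user_location = user_location,
    place_country = place_country, place_full_name = place_full_name,
    place_type = NA_character_, is_retweet = is_retweet, is_quote = is_quote
  )
}

v1_raw <- function(id = "1", text = "hello", user_id = "u1",
                   created_at = "Wed Sep 02 10:00:00 +0000 2020",
                   description = "", location = "", retweeted = FALSE,
                   quote = FALSE) {
  raw <- list(
    id_str = id, text = text, created_at = created_at,
    user = list(id_str = user_id, name = "name", description = description,
                location = location),
    is_quote_status = quote
  )
  if (retweeted) raw$retweeted_status <- list(id_str = "orig")
  raw
}

# Half-up percentage rounding oracle by digit-string long division:
# independent of the package's integer-arithmetic shortcut.
pct_oracle <- function(num, den, decimals) {
  N <- 100 * num
  q0 <- N %/% den
  r <- N %% den
  digits <- integer(decimals + 1)
  for (i in seq_len(decimals + 1)) {
    r <- r * 10
    digits[i] <- r %/% den
    r <- r %% den
  }
  kept <- if (decimals == 0) q0 else {
    q0 * 10^decimals + sum(digits[seq_len(decimals)] * 10^(decimals - seq_len(decimals)))
  }
  if (digits[decimals + 1] >= 5) kept <- kept + 1
  kept / 10^decimals
}

# Brute-force Cohen's kappa from the explicit agreement table.
kappa_oracle <- function(a, b) {
  lev <- sort(union(a, b))
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- 0
  for (l in lev) p_e <- p_e + mean(a == l) * mean(b == l)
  (p_o - p_e) / (1 - p_e)
}

default_ps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- compile_pattern_set()
    cache
  }
})

# minimal 2x2 pattern config for arithmetic-of-compilation tests
tiny_pattern_config <- function(tweet_templates = list(t1 = "i am a {identity} {person}"),
                                profile_templates = list(p1 = "{identity} {person}")) {
  list(
    identity_terms = c("gay", "bi"),
    person_terms = c("man", "guy"),
    people_terms = c("men", "guys"),
    tweet_templates = tweet_templates,
    profile_templates = profile_templates
  )
}
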