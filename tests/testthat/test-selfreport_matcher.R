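test_that("template expansion yields the identity x person cross-product", {
  ps <- compile_pattern_set(tiny_pattern_config())
  expect_equal(sum(ps$surface$channel == "tweet"), 4) # 2 identity x 2 person
  expect_equal(sum(ps$surface$channel == "profile"), 4)
})

test_that("config errors: unknown placeholders and empty term lists", {
  cfg <- tiny_pattern_config(tweet_templates = list(bad = "i am {adjective}"))
  expect_error(compile_pattern_set(cfg), class = "selfreportr_config_error")
  cfg <- tiny_pattern_config(); cfg$identity_terms <- character(0)
  expect_error(compile_pattern_set(cfg), class = "selfreportr_config_error")
  cfg <- tiny_pattern_config(); cfg$profile_templates <- list()
  expect_error(compile_pattern_set(cfg), class = "selfreportr_config_error")
  expect_s3_class(compile_pattern_set(), "pattern_set") # shipped default compiles
})

test_that("first-person anchors are required in the tweet channel", {
  ps <- default_ps()
  expect_null(match_tweet_text("I love my gay friends", ps))
  expect_null(match_tweet_text("gay rights are human rights", ps))
  m <- match_tweet_text("I'm a gay man and proud", ps)
  expect_equal(m$matched_text, "I'm a gay man")
  expect_equal(m$template_id, "first_person_identity")
})

test_that("short identity terms respect word boundaries", {
  ps <- default_ps()
  expect_null(match_tweet_text("I'm a big guy", ps))
  expect_null(match_tweet_text("I'm a bird man at heart", ps))
  expect_equal(match_tweet_text("I'm a bi guy", ps)$matched_text, "I'm a bi guy")
})

test_that("matching is deterministic and leftmost with template-order ties", {
  ps <- default_ps()
  txt <- "As a gay man, being a bi guy is something I know nothing about"
  m1 <- match_tweet_text(txt, ps)
  expect_equal(m1$matched_text, "As a gay man")
  expect_identical(match_tweet_text(txt, ps), m1)
  expect_equal(substr(txt, m1$start, m1$end - 1), m1$matched_text)
})

test_that("adding a template never removes a match", {
  cfg <- default_pattern_config()
  ps <- compile_pattern_set(cfg)
  texts <- c("I'm a gay man and proud", "As a bi guy I disagree",
             "gay men like me exist", "being a gay dude is fine")
  base <- lapply(texts, match_tweet_text, ps = ps)
  cfg$tweet_templates <- c(cfg$tweet_templates,
                           list(identify_as = "i identify as {identity}"))
  ps2 <- compile_pattern_set(cfg)
  for (i in seq_along(texts)) {
    m <- match_tweet_text(texts[i], ps2)
    expect_false(is.null(m), info = texts[i])
    expect_equal(m$matched_text, base[[i]]$matched_text)
  }
  expect_false(is.null(match_tweet_text("i identify as bisexual", ps2)))
})

test_that("profile matching scans description then display name, no anchor needed", {
  ps <- default_ps()
  u <- make_rec(user_description = "A proud black gay guy.")
  expect_equal(match_profile(u, ps)$matched_text, "gay guy")
  u2 <- make_rec(user_description = "runner and baker", user_name = "gay dude")
  m2 <- match_profile(u2, ps)
  expect_equal(m2$field, "user_name")
  u3 <- make_rec(user_description = "", user_name = "nothing here")
  expect_null(match_profile(u3, ps))
})

test_that("default mode reproduces decoy matches; strict mode excludes them", {
  ps <- default_ps()
  memorial <- "Today, we remember Matthew Shepard who’s life was cut short as a result of a hate crime due to his identity as a gay male."
  expect_false(is.null(match_tweet_text(memorial, ps)))
  expect_null(match_tweet_text(memorial, ps, mode = "strict"))

  trans_profile <- make_rec(
    user_description = "50+ gay trans man, writer, film and food lover. He/him OR they/them.")
  expect_false(is.null(match_profile(trans_profile, ps)))
  expect_null(match_profile(trans_profile, ps, mode = "strict"))

  # strict must not lose genuine first-person matches
  expect_false(is.null(match_tweet_text("I'm a gay man and proud", ps,
                                        mode = "strict")))
})

test_that("classify_user combines channels and applies the span rule", {
  ps <- default_ps()
  u <- consolidate_users(make_rec("t0", user_id = "u1",
                                  user_description = "plants and games"))
  tw <- make_rec("t1", "As a gay man I love this park", "u1")
  ev <- classify_user(tw, u, ps)
  expect_equal(ev$evidence, "tweet")
  expect_equal(ev$source_tweet_id, "t1")

  u_match <- consolidate_users(make_rec("t0", user_id = "u1",
                                        user_description = "Proud gay man."))
  expect_equal(classify_user(tw, u_match, ps)$evidence, "both")
  expect_equal(classify_user(tw[0, ], u_match, ps)$evidence, "profile")

  quoted <- make_rec("t2", '"I am a gay man," he said.', "u1")
  expect_null(classify_user(quoted, u, ps))

  mixed <- dplyr::bind_rows(tw, make_rec("t3", "hello", "OTHER"))
  expect_error(classify_user(mixed, u, ps), class = "selfreportr_contract_error")

  # earliest matching tweet is provenance
  two <- dplyr::bind_rows(
    make_rec("t5", "being a bi guy is fine", "u1", created_at = "2020-09-09 10:00:00"),
    make_rec("t4", "I'm a gay man ok", "u1", created_at = "2020-09-03 10:00:00")
  )
  expect_equal(classify_user(two, u, ps)$source_tweet_id, "t4")
})
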