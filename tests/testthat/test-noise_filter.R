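test_that("retweet flag semantics: quotes are not retweets", {
  expect_true(is_retweet(make_rec(is_retweet = TRUE)))
  expect_false(is_retweet(make_rec()))
  expect_false(is_retweet(make_rec(is_quote = TRUE)))
})

test_that("spans inside quotation regions are reported speech", {
  txt <- '"I am a gay man," he said.'
  s <- stringr::str_locate(txt, "I am a gay man")
  res <- detect_reported_speech(txt, c(s[1], s[2] + 1))
  expect_true(res$reported)
  expect_equal(res$trigger, "quotation")

  # curly quotes and unbalanced quotes (close at end-of-text)
  txt2 <- "“I am a bi guy and tired"
  s2 <- stringr::str_locate(txt2, "I am a bi guy")
  expect_true(detect_reported_speech(txt2, c(s2[1], s2[2] + 1))$reported)

  # span outside the quoted region is not reported speech
  txt3 <- 'He shouted "nonsense" but as a gay man I disagree entirely'
  s3 <- stringr::str_locate(txt3, "as a gay man")
  expect_false(detect_reported_speech(txt3, c(s3[1], s3[2] + 1))$reported)
})

test_that("a first-person tweet with no quotes or attribution is retained", {
  txt <- "As a bi guy we get so little representation, and almost all of its negative. It’s frustrating."
  s <- stringr::str_locate(txt, "As a bi guy")
  res <- detect_reported_speech(txt, c(s[1], s[2] + 1))
  expect_false(res$reported)
})

test_that("attribution-verb sentences are reported speech", {
  txt <- "Being a gay man is central to my art, the director said"
  s <- stringr::str_locate(txt, "Being a gay man")
  res <- detect_reported_speech(txt, c(s[1], s[2] + 1))
  expect_true(res$reported)
  expect_equal(res$trigger, "attribution")
})

test_that("the headline heuristic needs all three clauses and fires on them", {
  txt <- "Gay men say new policy is discriminatory https://t.co/x"
  hc <- selfreportr:::headline_clauses(txt, 0.1)
  expect_true(hc$no_first_person)
  expect_true(hc$ends_with_url)
  expect_true(hc$titlecase_ok)
  s <- stringr::str_locate(txt, "Gay men")
  res <- detect_reported_speech(txt, c(s[1], s[2] + 1))
  expect_true(res$reported)
  expect_equal(res$trigger, "headline")

  # same text without the URL: no rule can fire
  txt2 <- "Gay men celebrate new policy"
  expect_false(detect_reported_speech(txt2, c(1, 8))$reported)
  # first-person pronoun defeats the headline rule even with a URL
  txt3 <- "Gay men like me love this https://t.co/x"
  expect_false(detect_reported_speech(txt3, c(1, 8))$reported)
})

test_that("each reported-speech rule is independently toggleable", {
  txt <- '"I am a gay man" indeed.'
  s <- stringr::str_locate(txt, "I am a gay man")
  span <- c(s[1], s[2] + 1)
  expect_true(detect_reported_speech(txt, span)$reported)
  expect_false(detect_reported_speech(txt, span, rs_config(quotation = FALSE))$reported)

  txt2 <- "Gay men say new policy is discriminatory https://t.co/x"
  expect_false(detect_reported_speech(txt2, c(1, 8), rs_config(headline = FALSE))$reported)
})

test_that("invalid spans are contract errors", {
  expect_error(detect_reported_speech("short", c(0, 3)),
               class = "selfreportr_contract_error")
  expect_error(detect_reported_speech("short", c(3, 3)),
               class = "selfreportr_contract_error")
  expect_error(detect_reported_speech("short", c(2, 99)),
               class = "selfreportr_contract_error")
})

test_that("reported speech never fires without quotes, attribution verbs, or URLs", {
  texts <- c(
    "As a gay man I think this city needs better transit",
    "Being a bi guy in this town is wild sometimes",
    "I'm a gay man and I'm not hiding it anymore",
    "Honestly gay men like me just want a quiet weekend",
    "The festival was loud and the food was excellent"
  )
  withr::with_seed(99, {
    for (txt in texts) {
      n <- nchar(txt)
      for (k in 1:10) {
        st <- sample(n - 1, 1)
        en <- sample((st + 1):(n + 1), 1)
        expect_false(detect_reported_speech(txt, c(st, en))$reported, info = txt)
      }
    }
  })
})

test_that("filter_stream partitions the input and preserves order", {
  recs <- dplyr::bind_rows(
    make_rec("t1"), make_rec("t2", is_retweet = TRUE), make_rec("t3")
  )
  fl <- filter_stream(recs)
  expect_equal(fl$retained$tweet_id, c("t1", "t3"))
  expect_equal(nrow(fl$decisions), 3)
  expect_equal(sum(fl$decisions$verdict == "drop_retweet"), 1)
  expect_true(all(nzchar(fl$decisions$trigger[fl$decisions$verdict != "retain"])))
  # retained + dropped = input, disjoint
  dropped <- fl$decisions$tweet_id[fl$decisions$verdict != "retain"]
  expect_setequal(c(fl$retained$tweet_id, dropped), recs$tweet_id)
  expect_length(intersect(fl$retained$tweet_id, dropped), 0)
  # re-running yields identical decisions
  expect_identical(filter_stream(recs)$decisions, fl$decisions)

  expect_equal(nrow(filter_stream(recs[0, ])$retained), 0)
  all_rt <- dplyr::bind_rows(make_rec("a", is_retweet = TRUE),
                             make_rec("b", is_retweet = TRUE))
  expect_equal(nrow(filter_stream(all_rt)$retained), 0)
})
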