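test_that("generation is deterministic under a fixed seed, down to file bytes", {
  spec <- corpus_spec(n_users = 150, seed = 12)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth, c2$truth)

  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(c1, f1); write_corpus(c2, f2)
  expect_identical(readLines(f1), readLines(f2))

  c3 <- generate_corpus(corpus_spec(n_users = 150, seed = 13))
  expect_false(identical(c1$records, c3$records))
})

test_that("spec validation rejects impossible mixtures", {
  expect_error(corpus_spec(tp_tweet_rate = 0.9, tp_profile_rate = 0.5))
  expect_error(corpus_spec(geo_coverage = 1.2))
  expect_error(corpus_spec(age_distribution = c(a = 1)),
               class = "selfreportr_config_error")
})

test_that("generator and pipeline are co-tested: every role behaves as built", {
  corp <- generate_corpus(corpus_spec(n_users = 400, seed = 21))
  ps <- default_ps()
  truth <- corp$truth
  rec <- corp$records

  # genuine tweet self-reports always match the default pattern set
  tp_ids <- truth$user_id[truth$role == "tp_tweet"]
  tp_tweets <- rec[rec$user_id %in% tp_ids & !rec$is_retweet, ]
  matched_users <- unique(tp_tweets$user_id[
    !is.na(selfreportr:::match_texts(tp_tweets$text, ps, "tweet")$start)])
  expect_setequal(matched_users, tp_ids)

  # genuine profiles always match; trans/nonbinary decoys match in default
  users <- consolidate_users(rec)
  for (r in c("tp_profile", "fp_transnb")) {
    ids <- truth$user_id[truth$role == r]
    prof <- users[users$user_id %in% ids, ]
    hits <- selfreportr:::match_texts(prof$user_description, ps, "profile")
    expect_false(anyNA(hits$start), info = r)
  }

  # retweet-role users' identity content is always flagged as retweets
  rt_ids <- truth$user_id[truth$role == "retweet"]
  rt_rec <- rec[rec$user_id %in% rt_ids, ]
  rt_matches <- selfreportr:::match_texts(rt_rec$text, ps, "tweet")
  expect_true(all(rt_rec$is_retweet[!is.na(rt_matches$start)]))

  # quoted self-reports are always caught by the span rule
  rs_ids <- truth$user_id[truth$role == "reported_speech"]
  rs_rec <- rec[rec$user_id %in% rs_ids, ]
  m <- selfreportr:::match_texts(rs_rec$text, ps, "tweet")
  for (i in which(!is.na(m$start))) {
    expect_true(detect_reported_speech(rs_rec$text[i],
                                       c(m$start[i], m$end[i]))$reported)
  }

  # truth consistency: TP users carry a matching record or profile
  expect_true(all(truth$role[truth$is_true_positive] %in%
                    c("tp_tweet", "tp_profile")))
})

test_that("a decoy-free corpus yields perfect precision and recall", {
  spec <- corpus_spec(n_users = 200, tp_tweet_rate = 1, tp_profile_rate = 0,
                      fp_thirdperson_rate = 0, fp_transnb_rate = 0,
                      retweet_rate = 0, reported_speech_rate = 0, seed = 8)
  corp <- generate_corpus(spec)
  sc <- score_pipeline(run_pipeline(corp$records)$cohort, corp$truth)
  expect_equal(sc$precision, 1.0)
  expect_equal(sc$recall, 1.0)
})

test_that("an all-decoy corpus yields zero precision in default mode", {
  spec <- corpus_spec(n_users = 100, tp_tweet_rate = 0, tp_profile_rate = 0,
                      fp_thirdperson_rate = 1, fp_transnb_rate = 0,
                      retweet_rate = 0, reported_speech_rate = 0, seed = 9)
  corp <- generate_corpus(spec)
  cohort <- run_pipeline(corp$records)$cohort
  expect_gt(nrow(cohort), 0) # the decoys are matched, as designed
  expect_equal(score_pipeline(cohort, corp$truth)$precision, 0)
})

test_that("score_pipeline enforces truth coverage and handles empty cohorts", {
  corp <- generate_corpus(corpus_spec(n_users = 50, seed = 14))
  stranger <- tibble::tibble(user_id = "nobody", state = NA, county = NA,
                             age = NA)
  expect_error(score_pipeline(stranger, corp$truth),
               class = "selfreportr_contract_error")
  empty <- corp$truth[0, c("user_id", "state", "county", "age")]
  sc <- score_pipeline(empty, corp$truth)
  expect_true(is.na(sc$precision))
  expect_equal(sc$recall, 0)
})

test_that("v1 corpus files re-ingest to the same stream", {
  corp <- generate_corpus(corpus_spec(n_users = 60, seed = 33))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corp, f, dialect = "v1")
  back <- read_tweet_stream(f, dialect = "v1")
  expect_equal(read_report(back)$n_skipped, 0)
  expect_equal(back$tweet_id, corp$records$tweet_id)
  expect_equal(back$text, corp$records$text)
  expect_equal(back$is_retweet, corp$records$is_retweet)
  expect_equal(back$created_at, corp$records$created_at)
  expect_equal(back$user_location, corp$records$user_location)
})
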