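test_that("build_cohort is the deduplicating union with both-evidence", {
  co <- build_cohort(c("A", "B"), c("B", "C"))
  expect_equal(nrow(co), 3)
  expect_equal(co$evidence[co$user_id == "B"], "both")
  expect_equal(nrow(build_cohort(c("a", "b"), c("c", "d", "e"))), 5)
  expect_equal(nrow(build_cohort(character(0), character(0))), 0)
  # size is always |tweet set union profile set|
  withr::with_seed(5, {
    for (i in 1:20) {
      tw <- sample(letters, sample(0:20, 1))
      pr <- sample(letters, sample(0:20, 1))
      expect_equal(nrow(build_cohort(tw, pr)), length(union(tw, pr)))
    }
  })
})

test_that("pct uses exact half-up rounding and enforces its contract", {
  expect_equal(pct(417, 500, 1), 83.4)
  expect_equal(pct(430, 500, 0), 86)
  expect_equal(pct(0, 500, 1), 0.0)
  expect_equal(pct(535, 6240, 1), 8.6)
  expect_equal(pct(1, 8, 2), 12.5)  # exact terminating decimal
  expect_equal(pct(1, 800, 1), 0.1) # exact tie 0.125 rounds up, not to even
  expect_error(pct(1, 0, 1), class = "selfreportr_contract_error")
  expect_error(pct(5, 4, 1), class = "selfreportr_contract_error")
  expect_error(pct(1.5, 4, 1), class = "selfreportr_contract_error")
})

test_that("pct agrees with the long-division rounding oracle", {
  withr::with_seed(31, {
    for (i in 1:300) {
      den <- sample(1:20000, 1)
      num <- sample(0:den, 1)
      d <- sample(0:3, 1)
      expect_equal(pct(num, den, d), pct_oracle(num, den, d),
                   info = paste(num, den, d))
    }
  })
})

test_that("county_table applies the threshold with the county-resolved denominator", {
  cohort <- tibble::tibble(
    user_id = as.character(1:230),
    state = c(rep("CA", 120), rep("IL", 90), rep("TX", 20)),
    county = c(rep("Los Angeles County", 120), rep("Cook County", 90),
               rep(NA_character_, 20))
  )
  tab <- county_table(cohort, min_count = 100)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$county, "Los Angeles County")
  expect_equal(tab$share_pct, pct(120, 210, 1)) # 210 county-resolved, not 230
  tab2 <- county_table(cohort, min_count = 50)
  expect_equal(tab2$n, c(120, 90))
  expect_true(all(tab2$n >= 50))
  expect_equal(nrow(county_table(cohort[0, ], 100)), 0)
})

test_that("state and age tables sum to their denominators", {
  cohort <- tibble::tibble(
    user_id = as.character(1:10),
    state = c(rep("CA", 4), rep("NY", 3), NA, NA, "TX"),
    county = NA_character_,
    age = c(20, 30, NA, 47, 19, 61, NA, NA, 33, NA),
    age_group = age_group(c(20, 30, NA, 47, 19, 61, NA, NA, 33, NA))
  )
  st <- state_table(cohort)
  expect_equal(sum(st$n), sum(!is.na(cohort$state)))
  at <- age_table(cohort)
  expect_equal(sum(at$n), sum(!is.na(cohort$age_group)))
  expect_equal(at$age_group, c("13-24", "25-34", "35-44", "45-54", "55+"))
  expect_equal(at$n[at$age_group == "13-24"], 2L)
  stats <- age_stats(cohort)
  expect_equal(stats$n, 6)
  expect_equal(stats$median, median(c(20, 30, 47, 19, 61, 33)))
  expect_warning(age_table(cohort[is.na(cohort$age), ]))
})

test_that("users aged 20 and 30 split 50/50 across the first two groups", {
  cohort <- tibble::tibble(user_id = c("a", "b"), age = c(20L, 30L),
                           age_group = age_group(c(20, 30)))
  at <- age_table(cohort)
  expect_equal(at$n[1:2], c(1L, 1L))
  expect_equal(at$share_pct[1:2], c(50.0, 50.0))
})

test_that("jurisdiction overlap counts county or state membership", {
  lists <- default_jurisdiction_lists()
  cohort <- tibble::tibble(
    user_id = as.character(1:10),
    state = c("GA", "AL", "WY", "WY", "WY", "WY", "WY", "CA", "NY", "MT"),
    county = c("Fulton County", rep(NA_character_, 7), "New York County", NA)
  )
  ov <- jurisdiction_overlap(cohort, lists$ehe, "state_resolved")
  # Fulton County GA (county clause), AL (state clause), New York County NY
  expect_equal(ov$numerator, 3)
  expect_equal(ov$denominator, 10)
  expect_equal(ov$share_pct, 30.0)

  top10 <- lists$top10_hiv_states
  cohort2 <- tibble::tibble(user_id = as.character(1:10),
                            state = c(rep("CA", 5), rep("WY", 5)),
                            county = NA_character_)
  ov2 <- jurisdiction_overlap(cohort2, top10, "state_resolved")
  expect_equal(ov2$share_pct, 50.0)

  empty <- tibble::tibble(user_id = "x", state = NA_character_,
                          county = NA_character_)
  expect_error(jurisdiction_overlap(empty, top10, "state_resolved"),
               class = "selfreportr_contract_error")
})

test_that("shipped jurisdiction lists validate against the gazetteer", {
  g <- default_gazetteer()
  lists <- default_jurisdiction_lists()
  expect_length(lists$top10_hiv_states$states, 10)
  expect_true(all(lists$ehe$counties$state %in% g$states$usps))
  expect_gt(nrow(lists$ehe$counties), 40)
  # a list with entries missing from the gazetteer is rejected
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("kind,name,state", "county,Atlantis County,FL"), f)
  expect_error(load_jurisdiction_list(f, gazetteer = g),
               class = "selfreportr_jurisdiction_error")
})
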