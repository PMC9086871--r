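Package: selfreportr
Title: High-Precision Identification of Self-Reported Cohorts in Social
    Media Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An automated natural language processing pipeline for
    identifying social media users in the United States who self-report
    being gay, bisexual, or men who have sex with men (MSM), for use in
    digital epidemiology and PrEP-related intervention research. Reads
    Twitter-style JSON Lines streams (v1.1 and flattened v2 dialects),
    removes retweets and reported speech (quotations, attributions, news
    headlines), matches first-person self-reports in tweet text and user
    profiles with a configurable high-precision template grammar, resolves
    US state- and county-level geolocation from profile strings via a
    gazetteer, extracts self-reported ages, and produces demographic
    summaries and HIV priority-jurisdiction overlaps. Includes an
    annotation-based evaluation layer (Cohen's kappa, precision) and a
    seeded synthetic-corpus generator with ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
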