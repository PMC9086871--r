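---
title: "Identifying self-reported MSM cohorts in tweet streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying self-reported MSM cohorts in tweet streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfreportr)
```

## The procedure and its assumptions

`selfreportr` assembles a cohort of US-based users who *self-report*
being gay, bisexual, or MSM from a stream of tweet objects. The
underlying assumptions are those of high-precision infoveillance work:

* A *self-report* is a first-person statement by the author about their
  own identity. Identity terms in third-person mentions, quotations,
  attributed statements, or headlines are not self-reports, so the
  pipeline removes retweets wholesale and tests every candidate match
  against reported-speech rules.
* Profile descriptions are self-descriptive by convention, so profile
  matching does not require a first-person anchor ("Proud gay guy." is
  evidence; the same phrase inside a news tweet is not).
* Precision is privileged over recall throughout: ambiguous place names
  resolve to nothing rather than a guess, age patterns are first-person
  anchored, and the matcher is a small closed template grammar rather
  than a learned classifier.

The pipeline runs in the order: retweet removal → tweet-text matching
with span-conditional reported-speech exclusion → profile matching →
cross-channel deduplication (`evidence ∈ {tweet, profile, both}`) →
geolocation → age resolution → demographic reporting. Reported speech is
*not* a blanket pre-filter: the quotation and attribution rules need the
candidate span's position, so they run at match time.

## The matcher: a template grammar at a measured operating point

The shipped grammar (`inst/extdata/patterns_default.yaml`) crosses
identity terms (*gay, bi, bisexual, homosexual, msm, men who have sex
with men*) with person terms (*man, guy, male, dude, boy* and plurals)
through first-person templates for tweets and collocation templates for
profiles. Compilation is case-insensitive with word-boundary semantics —
"bi" never fires inside "big" or "bird" — and templates admit up to two
intervening modifier words, so "gay **trans** man" still matches.
Overlaps resolve leftmost-first, ties by template list order.

A deliberate design choice: the **default mode reproduces the measured
false-positive behavior**. Third-person memorial tweets ("… due to his
identity as a gay male") and transgender/nonbinary profiles ("50+ gay
trans man … They/them.") *do* match, because the published precision of
such a pipeline (about 0.85) is defined against exactly that behavior,
with human annotation separating true from false positives. The
`strict` mode — third-person-possessive and trans/nonbinary exclusions —
is clearly an extension: on synthetic corpora it strictly increases
precision without increasing recall, but it is not the measured
operating point.

## Reported-speech rules

Three independently toggleable rules (`rs_config()`):

* **quotation** — the span lies strictly inside a quotation-delimited
  region. Straight double quotes pair sequentially; curly doubles and
  singles pair by open/close type (a lone right single quote is an
  apostrophe); unbalanced openers close at end-of-text.
* **attribution** — the sentence containing the span ends with an
  attribution verb (said/says/told/wrote/tweeted/…) preceded by an
  optional subject, as in "…, he said."
* **headline** — the whole text reads like a news item: *no*
  first-person pronoun anywhere, *and* it ends with a URL, *and* its
  title-case word density is at least `titlecase_threshold`.

The three headline clauses are conjunctive. This is the one place the
rule family was genuinely open: making the URL clause optional would
catch more headlines but would let a quote-free, verb-free text trigger
the detector, violating the invariant that reported speech is never
declared without quotes, an attribution verb, or a URL. With the URL
clause mandatory, the title-case threshold defaults to a permissive 0.1
(headlines are usually sentence-case, so "Gay men say new policy is
discriminatory https://…" has density 1/7); the pronoun and URL clauses
carry the specificity. Quote-tweets are retained and judged by the span
rule rather than dropped wholesale — dropping them would discard genuine
first-person commentary around a quoted passage.

## Geolocation

Free-text locations are tokenized on commas/slashes and matched
case-insensitively with precedence **aliases → cities → counties →
states**; structured place metadata (when present and US) takes priority
over profile text. Choices worth knowing:

* Ambiguous city names without a state hint ("Springfield", "Portland")
  resolve to nothing — precision first. A state hint ("Portland, ME")
  disambiguates.
* "nyc" and "New York City" map to New York County (Manhattan); the five
  boroughs are separate gazetteer entries, since county tables
  conventionally list New York County and Kings County separately.
* Washington DC is both a state-level and a county-level unit, and is
  counted in both denominators.
* A token equal to a state name is always a state ("New York" alone is
  the state, not the city); emoji-only and non-Latin strings resolve to
  nothing.

## Ages

Patterns are first-person anchored ("I'm 24", "I'm 24 years old",
"turned 30", "my 21st birthday"), with a percent guard ("I'm 100% sure"
is not an age) and a [0, 130] sanity range. A user's age comes from
their **most recent** age-bearing tweet; within a tweet (or on a
timestamp tie) the **largest** value wins, guarding against "I'm 5 foot
… I'm 24". Ages below 13 are discarded entirely. Birth-year arithmetic
("born in 1995") is available behind `age_config(include_birth_year =
TRUE)` but off by default, since it is an inference rather than a direct
self-report.

## Evaluation layer

Annotation sampling is per channel, uniform without replacement, seeded,
and non-overlapping across channels. **Cohen's κ is computed on the
pre-adjudication labels** — that is what "independent dual annotation"
measures — while **precision is computed on the post-adjudication final
labels**. The degenerate κ case (both annotators constant and
identical, p_e = 1) is defined as 1 with a warning. A channel with no
annotated records has absent metrics, never zeros.

## Percentage arithmetic

Published tables use half-up rounding, so `pct()` implements half-up
(not banker's) via exact integer arithmetic,
`floor((200·num·10^d + den) / (2·den)) / 10^d`, which is exact for all
count pairs and agrees with a long-division oracle. One published ratio
is *not* reproducible under any standard rounding: a county-coverage
share printed as 71.2% whose exact value is 71.265…% (→ 71.3 half-up).
The package treats this as a probable truncation or typo in the source
table: the value is documented and asserted as 71.3, not chased.

## What the synthetic generator emulates — and what it does not

`corpus_spec()` defaults encode the observed stream conditions: state
geolocation coverage 0.876, county coverage 0.712 of state-resolved
users, age coverage 0.476, the observed five-bin age mix, state weights
skewed toward the eight highest-volume states, and decoy rates chosen so
the expected channel-level false-positive shares are 16.6% (tweets) and
14% (profiles) — an overall analytic precision of about 0.844. Each
user receives exactly one role (genuine tweet/profile self-report,
third-person decoy, trans/nonbinary decoy, retweet-only, quoted-speech
only, background), so the measured precision of a pipeline run is a
binomial draw around the analytic mixture value
`(tp_t + tp_p) / (tp_t + tp_p + fp_3p + fp_tnb)`.

The generator writes the v1.1 dialect by default and is byte-identical
under a fixed seed. It emulates the *statistical structure* the pipeline
assumes — not real Twitter. Texts are minimal paraphrase families around
annotated exemplars; there is no slang drift, typo noise, multilingual
content, bot traffic, or adversarial phrasing. Consequently, passing
synthetic tests shows the pipeline's *mechanics* are correct (recall 1.0
against its own template space, exact geolocation/age recovery,
precision at the designed mixture), not that these rates transfer to a
live stream. Observed live-stream magnitudes (a 10,043-user cohort, κ of
0.81/0.83/0.79, coverage 87.6%/71.2%/47.6% as *empirical* coverage,
mean/median ages 31.9/29) depend on the 2020–2021 stream and are
reference values only.

## Problem sizes and numerical choices

Test corpora use 150–3000 users; the acceptance workload uses a
10,000-user corpus (≈ 25,000 records, under a minute end-to-end on one
core), with statistical assertions at ±3 binomial standard errors.
Profile-recency ties break on the lexicographically larger tweet id;
records with unparseable timestamps are kept with a sentinel minimal
timestamp and a warning rather than dropped, so the cohort never shrinks
silently; malformed JSON lines are skipped and counted, with a
wrong-dialect error when they exceed half the file.

## Known limitations

* English-only; attribution verbs and pronoun lists are English.
* The grammar is a reconstruction: it reproduces all published example
  behaviors, but it is not the original (unpublished) regex inventory.
  The YAML config is the drop-in point if that inventory is obtained.
* Gazetteer coverage is intentionally compact (51 states, ~85 counties,
  ~82 cities); real profile strings resolve at lower rates than
  synthetic ones.
* Recall is unmeasured by design — estimating it would require
  annotating non-matched users.
* Identification of transgender and nonbinary users is explicitly out of
  scope; the strict mode excludes, rather than classifies, such
  profiles.
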