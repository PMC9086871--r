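# Annotation-based evaluation: per-channel sampling, Cohen's kappa on the
# independent dual annotations, adjudication of disagreements, precision
# on the final labels.

#' Sample cohort units for annotation
#'
#' Uniform without-replacement sample per evidence channel, reproducible
#' from `seed`. Tweet-channel units are drawn from users with tweet (or
#' both) evidence; profile-channel units from the remaining users with
#' profile (or both) evidence, so no user is annotated twice.
#'
#' @param cohort Cohort tibble (`user_id`, `evidence`).
#' @param n_tweets,n_profiles Sample sizes per channel.
#' @param seed Integer seed.
#' @return Tibble `unit_id`, `channel`.
#' @export
sample_for_annotation <- function(cohort, n_tweets = 500, n_profiles = 500,
                                  seed = 1L) {
  tweet_pool <- sort(cohort$user_id[cohort$evidence %in% c("tweet", "both")])
  if (length(tweet_pool) < n_tweets) {
    abort(paste0("Cannot sample ", n_tweets, " tweet units from ",
                 length(tweet_pool), " eligible users."),
          class = "selfreportr_sampling_error")
  }
  withr::with_seed(seed, {
    s_t <- sample(tweet_pool, n_tweets)
    profile_pool <- sort(setdiff(
      cohort$user_id[cohort$evidence %in% c("profile", "both")], s_t))
    if (length(profile_pool) < n_profiles) {
      abort(paste0("Cannot sample ", n_profiles, " profile units from ",
                   length(profile_pool), " eligible users."),
            class = "selfreportr_sampling_error")
    }
    s_p <- sample(profile_pool, n_profiles)
  })
  tibble::tibble(
    unit_id = c(s_t, s_p),
    channel = rep(c("tweet", "profile"), c(n_tweets, n_profiles))
  )
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between two annotators:
#' `kappa = (p_o - p_e) / (1 - p_e)` with the expected agreement `p_e`
#' computed from each annotator's marginal label frequencies. In the
#' degenerate case where both annotators are constant and identical
#' (`p_e = 1`), kappa is defined as 1 with a warning.
#'
#' @param labels_a,labels_b Equal-length label vectors, length >= 2.
#' @return The agreement coefficient in \[-1, 1\].
#' @examples
#' cohen_kappa(rep(c("TP", "FP"), 5), rep(c("TP", "FP"), 5))
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || length(labels_a) < 2) {
    abort("Label vectors must have equal length >= 2.",
          class = "selfreportr_contract_error")
  }
  lev <- sort(union(unique(labels_a), unique(labels_b)))
  tab <- table(factor(labels_a, levels = lev), factor(labels_b, levels = lev))
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    warn("Both annotators are constant and identical; kappa defined as 1.")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Resolve annotation disagreements
#'
#' Agreed records keep the agreed label as final; disagreements take the
#' supplied adjudicated label. A disagreement without an adjudication is
#' an error listing the affected unit ids.
#'
#' @param records Tibble with `unit_id`, `channel`, `label_a`, `label_b`
#'   (labels `"TP"`/`"FP"`).
#' @param adjudicated Optional tibble `unit_id`, `final`.
#' @return `records` with a `final` column set for every row.
#' @export
adjudicate <- function(records, adjudicated = NULL) {
  bad <- !records$label_a %in% c("TP", "FP") | !records$label_b %in% c("TP", "FP")
  if (any(bad)) {
    abort("Labels must be \"TP\" or \"FP\".", class = "selfreportr_contract_error")
  }
  records$final <- ifelse(records$label_a == records$label_b,
                          records$label_a, NA_character_)
  open <- which(is.na(records$final))
  if (length(open) > 0) {
    if (is.null(adjudicated)) {
      abort(paste0("Unadjudicated disagreements for unit_id: ",
                   paste(records$unit_id[open], collapse = ", ")),
            class = "selfreportr_adjudication_error")
    }
    idx <- match(records$unit_id[open], adjudicated$unit_id)
    missing <- records$unit_id[open][is.na(idx)]
    if (length(missing) > 0) {
      abort(paste0("Unadjudicated disagreements for unit_id: ",
                   paste(missing, collapse = ", ")),
            class = "selfreportr_adjudication_error")
    }
    records$final[open] <- adjudicated$final[idx]
  }
  records
}

channel_metrics <- function(rec) {
  if (nrow(rec) == 0) {
    return(list(n = 0L, tp = NA_integer_, fp = NA_integer_,
                precision = NA_real_, kappa = NA_real_))
  }
  tp <- sum(rec$final == "TP")
  fp <- sum(rec$final == "FP")
  kap <- if (all(c("label_a", "label_b") %in% names(rec)) &&
             !anyNA(rec$label_a) && !anyNA(rec$label_b) && nrow(rec) >= 2) {
    cohen_kappa(rec$label_a, rec$label_b)
  } else {
    NA_real_
  }
  list(n = nrow(rec), tp = tp, fp = fp, precision = tp / (tp + fp), kappa = kap)
}

#' Evaluation metrics from annotated records
#'
#' Precision (`TP / (TP + FP)`) per channel and pooled, computed on the
#' post-adjudication final labels; Cohen's kappa per channel and overall,
#' computed on the pre-adjudication independent labels (that is what dual
#' annotation measures). A channel with zero records has absent (`NA`)
#' metrics, not zeros.
#'
#' @param records Tibble with `unit_id`, `channel`, `final`, and (for
#'   kappa) `label_a`, `label_b`.
#' @return A list of class `eval_metrics` with fields `n_tweets`,
#'   `n_profiles`, `tp_tweets`, `fp_tweets`, `tp_profiles`, `fp_profiles`,
#'   `precision_tweets`, `precision_profiles`, `precision_overall`,
#'   `kappa_tweets`, `kappa_profiles`, `kappa_overall`.
#' @examples
#' rec <- tibble::tibble(
#'   unit_id = as.character(1:4), channel = c("tweet", "tweet", "profile", "profile"),
#'   label_a = c("TP", "TP", "TP", "FP"), label_b = c("TP", "FP", "TP", "FP")
#' )
#' rec <- adjudicate(rec, tibble::tibble(unit_id = "2", final = "TP"))
#' compute_metrics(rec)
#' @export
compute_metrics <- function(records) {
  if (!"final" %in% names(records) || anyNA(records$final)) {
    abort("All records must carry a final label; run adjudicate() first.",
          class = "selfreportr_contract_error")
  }
  tw <- channel_metrics(records[records$channel == "tweet", , drop = FALSE])
  pr <- channel_metrics(records[records$channel == "profile", , drop = FALSE])
  ov <- channel_metrics(records)
  structure(
    list(
      n_tweets = tw$n, n_profiles = pr$n,
      tp_tweets = tw$tp, fp_tweets = tw$fp,
      tp_profiles = pr$tp, fp_profiles = pr$fp,
      precision_tweets = tw$precision, precision_profiles = pr$precision,
      precision_overall = ov$precision,
      kappa_tweets = tw$kappa, kappa_profiles = pr$kappa,
      kappa_overall = ov$kappa
    ),
    class = "eval_metrics"
  )
}

#' @export
print.eval_metrics <- function(x, ...) {
  fmt <- function(v, d = 2) ifelse(is.na(v), "-", formatC(v, digits = d, format = "f"))
  cat("<eval_metrics>\n")
  cat("  tweets:   n =", x$n_tweets, " TP =", x$tp_tweets, " FP =", x$fp_tweets,
      " precision =", fmt(x$precision_tweets),
      " kappa =", fmt(x$kappa_tweets), "\n")
  cat("  profiles: n =", x$n_profiles, " TP =", x$tp_profiles, " FP =", x$fp_profiles,
      " precision =", fmt(x$precision_profiles),
      " kappa =", fmt(x$kappa_profiles), "\n")
  cat("  overall:  precision =", fmt(x$precision_overall),
      " kappa =", fmt(x$kappa_overall), "\n")
  invisible(x)
}

#' Read / write annotation sheets
#'
#' Annotation I/O is CSV with a fixed header (`unit_id`, `channel`,
#' `text`, `label_a`, `label_b`, `adjudicated`) so annotators can work in
#' spreadsheets.
#'
#' @param path CSV path.
#' @return `read_annotations()`: a tibble with the fixed columns.
#' @export
read_annotations <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  needed <- c("unit_id", "channel", "label_a", "label_b")
  if (!all(needed %in% names(out))) {
    abort(paste0("Annotation CSV must have columns: ",
                 paste(needed, collapse = ", ")),
          class = "selfreportr_contract_error")
  }
  out
}

#' @rdname read_annotations
#' @param units Tibble from [sample_for_annotation()], optionally with a
#'   `text` column of the evidence to judge.
#' @export
write_annotation_sheet <- function(units, path) {
  sheet <- tibble::tibble(
    unit_id = units$unit_id,
    channel = units$channel,
    text = if ("text" %in% names(units)) units$text else "",
    label_a = "", label_b = "", adjudicated = ""
  )
  readr::write_csv(sheet, path)
  invisible(path)
}
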