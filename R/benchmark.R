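# Practice-level benchmarking: per-measure pass rates with
# NOT_APPLICABLE / NOT_EVALUABLE excluded from denominators, and outlier
# flagging by an exact binomial central interval at the pooled national
# rate. The interval rule (and alpha, and the optional Bonferroni switch)
# is reported in the output metadata rather than hidden.

#' Summarize scorecards per practice
#'
#' @param scorecards list of `rt_scorecard` objects
#' @param practice_of named character vector / list mapping patient_key to
#'   practice label; every scored patient must be mapped
#' @return data.frame(practice, measure_id, n_evaluable, n_pass, pass_rate)
#'   with `pass_rate = NA` where `n_evaluable = 0`
#' @export
summarize_practices <- function(scorecards, practice_of) {
  practice_of <- unlist(practice_of)
  rows <- list()
  for (sc in scorecards) {
    pr <- if (sc$patient_key %in% names(practice_of))
      practice_of[[sc$patient_key]] else NA_character_
    if (is.null(pr) || is.na(pr))
      rtqa_error(paste("patient not mapped to a practice:", sc$patient_key),
                 "rtqa_wiring_error")
    for (r in sc$results)
      rows[[length(rows) + 1L]] <- data.frame(
        practice = pr, measure_id = r$measure_id, result = r$result)
  }
  long <- do.call(rbind, rows)
  out <- list()
  for (pr in sort(unique(long$practice))) {
    for (m in sort(unique(long$measure_id))) {
      sub <- long[long$practice == pr & long$measure_id == m, ]
      ev <- sub$result %in% c("PASS", "FAIL")
      n_ev <- sum(ev); n_pass <- sum(sub$result == "PASS")
      out[[length(out) + 1L]] <- data.frame(
        practice = pr, measure_id = m, n_evaluable = n_ev, n_pass = n_pass,
        pass_rate = if (n_ev > 0) n_pass / n_ev else NA_real_)
    }
  }
  do.call(rbind, out)
}

#' Pool practice summaries into national per-measure rates
#'
#' @param summaries output of [summarize_practices()]
#' @return data.frame(measure_id, n_evaluable, n_pass, pass_rate)
#' @export
pool_national <- function(summaries) {
  out <- list()
  for (m in sort(unique(summaries$measure_id))) {
    sub <- summaries[summaries$measure_id == m, ]
    n_ev <- sum(sub$n_evaluable); n_pass <- sum(sub$n_pass)
    out[[length(out) + 1L]] <- data.frame(
      measure_id = m, n_evaluable = n_ev, n_pass = n_pass,
      pass_rate = if (n_ev > 0) n_pass / n_ev else NA_real_)
  }
  do.call(rbind, out)
}

#' Flag outlier practices by the exact binomial central interval
#'
#' A practice is flagged on a measure iff its pass count falls outside the
#' central (1 - alpha) acceptance region of Binomial(n, p_national) for its
#' own n: below `qbinom(alpha/2, n, p)` or above `qbinom(1 - alpha/2, n, p)`.
#' Practices with `n_evaluable = 0` are never flagged. No multiple-testing
#' correction is applied unless `bonferroni = TRUE`, in which case alpha is
#' divided by the number of practice x measure tests.
#'
#' @param summaries output of [summarize_practices()]
#' @param national output of [pool_national()] (defaults to pooling
#'   `summaries`)
#' @param alpha two-sided test level (default 0.05)
#' @param bonferroni divide alpha by the number of tests
#' @return object of class `rt_outlier_flags`: data.frame of flags
#'   (practice, measure_id, direction, practice_rate, national_rate,
#'   lower, upper) with the method parameters attached as attributes
#' @export
flag_outliers <- function(summaries, national = pool_national(summaries),
                          alpha = 0.05, bonferroni = FALSE) {
  ntests <- sum(summaries$n_evaluable > 0)
  a <- if (bonferroni && ntests > 0) alpha / ntests else alpha
  flags <- list()
  for (i in seq_len(nrow(summaries))) {
    row <- summaries[i, ]
    if (row$n_evaluable == 0L) next
    nat <- national[national$measure_id == row$measure_id, ]
    p <- nat$pass_rate
    if (is.na(p)) next
    lo <- stats::qbinom(a / 2, row$n_evaluable, p)
    hi <- stats::qbinom(1 - a / 2, row$n_evaluable, p)
    dir <- if (row$n_pass < lo) "BELOW" else if (row$n_pass > hi) "ABOVE"
           else NA_character_
    if (!is.na(dir))
      flags[[length(flags) + 1L]] <- data.frame(
        practice = row$practice, measure_id = row$measure_id,
        direction = dir, practice_rate = row$pass_rate, national_rate = p,
        lower = lo / row$n_evaluable, upper = hi / row$n_evaluable)
  }
  out <- if (length(flags)) do.call(rbind, flags) else
    data.frame(practice = character(), measure_id = character(),
               direction = character(), practice_rate = numeric(),
               national_rate = numeric(), lower = numeric(),
               upper = numeric())
  structure(out, method = "exact binomial central interval",
            alpha = alpha, bonferroni = bonferroni,
            class = c("rt_outlier_flags", "data.frame"))
}
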