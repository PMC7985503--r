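#' Neuroticism sum score from 12 dichotomous items
#'
#' The short-form Eysenck neuroticism scale consists of 12 agree/disagree
#' items; the score is the number of items endorsed, ranging 0-12.  Any
#' missing item excludes the respondent (complete cases only, no
#' imputation), returning `NA`.
#'
#' @param items length-12 vector; logical (`TRUE` = agree) or character
#'   in `c("agree", "disagree")`, with `NA` for missing responses.
#' @param n_items instrument length (default 12).
#' @return Integer score in `0:n_items`, or `NA` if any item is missing.
#' @examples
#' neuroticism_sum(rep(TRUE, 12))          # 12
#' neuroticism_sum(c(rep(TRUE, 11), NA))   # NA: incomplete response
#' @export
neuroticism_sum <- function(items, n_items = 12L) {
  if (is.character(items)) {
    ok <- is.na(items) | items %in% c("agree", "disagree")
    if (!all(ok)) stop("items must be 'agree', 'disagree' or NA")
    items <- items == "agree"
  }
  items <- as.logical(items)
  if (length(items) != n_items) {
    stop(sprintf("expected %d items, got %d", n_items, length(items)))
  }
  if (anyNA(items)) return(NA_integer_)
  sum(items)
}

#' Chronic-pain exposure score
#'
#' Converts per-region "pain for 3+ months" flags plus an all-over-body
#' flag into a 0-3 score: 0 for no chronic pain anywhere, 1 for one
#' region, 2 for two, and 3 for three or more regions or pain all over the
#' body.  The truncation at 3 admits whole-body pain without assuming it
#' is more severe than pain in several distinct regions.
#'
#' @param region_chronic logical vector of per-region chronic-pain flags.
#' @param all_over_body logical, chronic pain all over the body.
#' @return Integer score in `0:3` (`NA` if any input is missing).
#' @examples
#' chronic_pain_score(c(TRUE, TRUE, FALSE, FALSE), FALSE)  # 2
#' chronic_pain_score(logical(7), TRUE)                    # 3
#' @export
chronic_pain_score <- function(region_chronic, all_over_body = FALSE) {
  region_chronic <- as.logical(region_chronic)
  all_over_body <- as.logical(all_over_body)
  if (anyNA(region_chronic) || is.na(all_over_body)) return(NA_integer_)
  n <- sum(region_chronic)
  if (all_over_body || n >= 3L) return(3L)
  as.integer(n)
}

#' Count endorsed options of a multiple-choice item
#'
#' Questionnaire items that allow several answer options (e.g. kinds of
#' social activity, recent stressful events) are converted to the number
#' of substantive options endorsed.  Endorsing only "none of the above"
#' scores 0; endorsing it together with substantive options is rejected as
#' an inconsistent response rather than silently ignored.
#'
#' @param option_flags logical vector over the substantive options.
#' @param none_flag logical, the "none of the above" option.
#' @return Integer count (`NA` if any flag is missing).
#' @export
count_endorsements <- function(option_flags, none_flag = FALSE) {
  option_flags <- as.logical(option_flags)
  none_flag <- as.logical(none_flag)
  if (anyNA(option_flags) || is.na(none_flag)) return(NA_integer_)
  n <- sum(option_flags)
  if (none_flag && n > 0L) {
    stop("'none of the above' endorsed together with substantive options")
  }
  as.integer(n)
}
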