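#' Score the OSDI questionnaire
#'
#' Standard Ocular Surface Disease Index scoring: 12 items, each answered
#' 0-4 or left unanswered (`NA`); the score is
#' `sum(answered) * 100 / (4 * n_answered)`, ranging 0-100. A score over 13
#' counts as positive subjective symptoms.
#'
#' @param responses Numeric vector of 12 item scores in `0:4`, `NA` for
#'   unanswered items.
#' @return The OSDI score in `[0, 100]`.
#' @examples
#' compute_osdi(rep(4, 12)) # 100
#' compute_osdi(c(rep(2, 10), NA, NA)) # 50
#' @export
compute_osdi <- function(responses) {
  if (length(responses) != 12L) abort("OSDI has 12 items")
  ans <- responses[!is.na(responses)]
  if (length(ans) == 0) abort("all OSDI items unanswered: score undefined")
  if (any(ans < 0 | ans > 4)) abort("OSDI item scores must be in 0..4")
  sum(ans) * 100 / (4 * length(ans))
}

#' Apply the dry eye diagnostic rule
#'
#' Dry eye disease iff the tear-film breakup time is 5 s or less AND the
#' OSDI score is over 13 (boundary semantics exactly: TFBUT of 5.0 is
#' short; OSDI of 13 is not symptomatic). A censored TFBUT is only a lower
#' bound, so it can never establish a short TFBUT: censored eyes are
#' classified non-DED.
#'
#' @param tfbut_s Estimated TFBUT in seconds (vectorized).
#' @param osdi_score OSDI score in `[0, 100]` (vectorized).
#' @param censored Logical: is `tfbut_s` only a lower bound?
#' @return Character vector, `"DED"` or `"non-DED"`.
#' @examples
#' diagnose_dry_eye(5.0, 14) # DED: 5 s or less, over 13
#' diagnose_dry_eye(4.0, 13) # non-DED: 13 is not over 13
#' @export
diagnose_dry_eye <- function(tfbut_s, osdi_score, censored = FALSE) {
  if (any(is.na(osdi_score))) abort("OSDI score missing: the criteria cannot be evaluated")
  if (any(is.na(tfbut_s))) abort("TFBUT missing: the criteria cannot be evaluated")
  if (any(osdi_score < 0 | osdi_score > 100)) abort("OSDI score must be in [0, 100]")
  short <- !censored & tfbut_s <= 5.0
  symptomatic <- osdi_score > 13
  ifelse(short & symptomatic, "DED", "non-DED")
}

#' Diagnose a case table
#'
#' Adds `predicted_dx` to a per-eye case tibble. The OSDI score is taken
#' from `osdi_score` or computed from response columns `osdi_01` ...
#' `osdi_12`; the TFBUT from `tfbut_s` with an optional logical `censored`
#' column.
#'
#' @param cases A tibble with `tfbut_s`, optionally `censored`, and either
#'   `osdi_score` or the 12 response columns.
#' @return `cases` with `osdi_score` (if computed) and `predicted_dx`.
#' @export
diagnose_cases <- function(cases) {
  if (!"osdi_score" %in% names(cases)) {
    resp_cols <- sprintf("osdi_%02d", 1:12)
    if (!all(resp_cols %in% names(cases))) {
      abort("need either `osdi_score` or columns osdi_01..osdi_12")
    }
    cases$osdi_score <- apply(as.matrix(cases[resp_cols]), 1, compute_osdi)
  }
  censored <- if ("censored" %in% names(cases)) cases$censored else FALSE
  cases$predicted_dx <- diagnose_dry_eye(cases$tfbut_s, cases$osdi_score,
                                         censored = censored)
  cases
}
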