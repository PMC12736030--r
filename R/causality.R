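#' Summarize qualitative causality assessments across cases
#'
#' Aggregates the five categorical causality dimensions recorded on
#' spontaneous reports — time sequence, prior knowledge of the reaction,
#' dechallenge, rechallenge, and alternative cause — into one frequency
#' table per dimension, with the case count as denominator. Reports without
#' an assessment (or with a missing dimension) are counted as `unknown`
#' (for rechallenge, `none_or_unknown`; for alternative cause,
#' `no_information`). No causality score is computed: the output is purely
#' the categorical reporting profile.
#'
#' @param cases A `report_db` of case reports.
#' @return Named list of [freq_table()]s (`denominator_kind = "reports"`),
#'   one per dimension, each an exhaustive partition of the case set.
#' @export
summarize_causality <- function(cases) {
  n <- n_reports(cases)
  idx <- match(cases$reports$report_id, cases$causality$report_id)
  missing_level <- c(
    time_sequence = "unknown",
    prior_knowledge = "unknown",
    dechallenge = "unknown",
    rechallenge = "none_or_unknown",
    alternative_cause = "no_information"
  )
  out <- lapply(names(CAUSALITY_LEVELS), function(dim) {
    vals <- cases$causality[[dim]][idx]
    vals[is.na(vals)] <- missing_level[[dim]]
    freq_table(table(factor(vals, levels = CAUSALITY_LEVELS[[dim]])),
               denominator = n, kind = "reports", sort = FALSE)
  })
  setNames(out, names(CAUSALITY_LEVELS))
}
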