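# Controlled vocabularies shared across the package. Spontaneous-report
# fields are categorical by design: missingness is an explicit level
# ("not_reported"), never an empty string.

REPORTER_PROFESSIONS <- c(
  "physician", "pharmacist", "nurse",
  "other_health_professional", "consumer", "not_reported"
)

REPORTER_SETTINGS <- c("in_hospital", "out_of_hospital", "not_reported")

PATIENT_SEXES <- c("male", "female", "not_reported")

SERIOUSNESS_CRITERIA <- c(
  "fatal", "life_threatening", "hospital_admission",
  "prolonged_hospitalisation", "disability", "medically_significant"
)

REACTION_OUTCOMES <- c(
  "recovered", "recovering", "not_recovered",
  "recovered_with_sequelae", "fatal", "not_reported"
)

DRUG_ROLES <- c("suspect", "concomitant", "interaction")

CAUSALITY_LEVELS <- list(
  time_sequence = c("compatible", "incompatible", "unknown"),
  prior_knowledge = c("well_known", "known", "unknown"),
  dechallenge = c(
    "withdrawal_with_improvement", "withdrawal_without_improvement",
    "no_withdrawal", "fatal_or_irreversible", "unknown"
  ),
  rechallenge = c("positive", "negative", "none_or_unknown"),
  alternative_cause = c(
    "no_information", "ruled_out", "equally_or_less_plausible_alternative"
  )
)

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals, the
#' convention used when reporting percentages in regulatory tables. Base R's
#' [round()] rounds half to even, which disagrees on exact .5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.25, 1) # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  trunc(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale * sign(x)
}

# shared internal validators -------------------------------------------------

assert_enum <- function(x, levels, what, id = NULL) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    offender <- unique(x[bad])
    ctx <- if (!is.null(id)) paste0(" (report_id: ",
      paste(unique(id[bad]), collapse = ", "), ")") else ""
    abort(sprintf(
      "invalid %s value(s): %s%s. Allowed: %s",
      what, paste(offender, collapse = ", "), ctx,
      paste(levels, collapse = ", ")
    ), class = "vigicase_validation_error")
  }
  invisible(x)
}

abort_schema <- function(msg) abort(msg, class = "vigicase_schema_error")
abort_integrity <- function(msg) abort(msg, class = "vigicase_integrity_error")
abort_validation <- function(msg) abort(msg, class = "vigicase_validation_error")
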