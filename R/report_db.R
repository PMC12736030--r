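#' Spontaneous-report database container
#'
#' A `report_db` holds a set of spontaneous adverse drug reaction reports in
#' normalized relational form, mirroring the on-disk `csv_bundle` schema:
#' one row per report in `reports`, one row per drug entry in `drugs`, one
#' row per reaction entry in `reactions`, and (optionally) one row per report
#' in `causality` with the five qualitative causality-assessment fields.
#' Reports are one-to-many in both drugs and reactions, so a single flat
#' table cannot represent them without duplication.
#'
#' @param reports Tibble with columns `report_id`, `received_date` (Date),
#'   `reporter_profession`, `reporter_setting`, `patient_age` (years, `NA`
#'   allowed), `patient_sex`, `serious` (logical).
#' @param drugs Tibble with columns `report_id`, `drug_name`, `atc_code`,
#'   `role` (one of `suspect`, `concomitant`, `interaction`).
#' @param reactions Tibble with columns `report_id`, `pt_code`,
#'   `seriousness_criteria` (list-column of character vectors, possibly
#'   empty), `outcome`.
#' @param causality Optional tibble with columns `report_id`,
#'   `time_sequence`, `prior_knowledge`, `dechallenge`, `rechallenge`,
#'   `alternative_cause`. Defaults to an empty table.
#' @param validate Run [validate_report_db()] on the assembled object
#'   (default `TRUE`).
#'
#' @return An object of class `report_db`.
#' @export
report_db <- function(reports, drugs, reactions, causality = NULL,
                      validate = TRUE) {
  if (is.null(causality)) {
    causality <- tibble::tibble(
      report_id = character(), time_sequence = character(),
      prior_knowledge = character(), dechallenge = character(),
      rechallenge = character(), alternative_cause = character()
    )
  }
  db <- structure(
    list(
      reports = tibble::as_tibble(reports),
      drugs = tibble::as_tibble(drugs),
      reactions = tibble::as_tibble(reactions),
      causality = tibble::as_tibble(causality)
    ),
    class = "report_db"
  )
  if (validate) validate_report_db(db)
  db
}

#' Validate a report database against the domain invariants
#'
#' Checks the structural and semantic invariants of the spontaneous-report
#' model: key columns present; every report has at least one drug and one
#' reaction; no orphan drug/reaction/causality rows; ages within \[0, 120\];
#' all categorical fields drawn from their controlled vocabularies; ATC codes
#' syntactically valid; a fatal reaction outcome implies the `fatal`
#' seriousness criterion; and the report-level `serious` flag consistent with
#' the reaction-level criteria (serious iff any reaction carries any
#' seriousness criterion).
#'
#' @param db A [report_db()] object.
#' @return `db`, invisibly, if valid. Otherwise aborts with a
#'   `vigicase_schema_error`, `vigicase_integrity_error` or
#'   `vigicase_validation_error` naming the offending column or report ids.
#' @export
validate_report_db <- function(db) {
  stopifnot(inherits(db, "report_db"))
  need <- list(
    reports = c("report_id", "received_date", "reporter_profession",
                "reporter_setting", "patient_age", "patient_sex", "serious"),
    drugs = c("report_id", "drug_name", "atc_code", "role"),
    reactions = c("report_id", "pt_code", "seriousness_criteria", "outcome"),
    causality = c("report_id", names(CAUSALITY_LEVELS))
  )
  for (tbl in names(need)) {
    missing <- setdiff(need[[tbl]], names(db[[tbl]]))
    if (length(missing) > 0) {
      abort_schema(sprintf("%s table is missing column(s): %s",
                           tbl, paste(missing, collapse = ", ")))
    }
  }
  ids <- db$reports$report_id
  if (anyDuplicated(ids)) {
    abort_integrity(sprintf("duplicate report_id(s): %s",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (tbl in c("drugs", "reactions", "causality")) {
    orphan <- setdiff(db[[tbl]]$report_id, ids)
    if (length(orphan) > 0) {
      abort_integrity(sprintf("orphan %s rows for report_id(s): %s",
                              tbl, paste(orphan, collapse = ", ")))
    }
  }
  no_drug <- setdiff(ids, db$drugs$report_id)
  if (length(no_drug) > 0) {
    abort_integrity(sprintf("report(s) with no drug entry: %s",
                            paste(no_drug, collapse = ", ")))
  }
  no_rxn <- setdiff(ids, db$reactions$report_id)
  if (length(no_rxn) > 0) {
    abort_integrity(sprintf("report(s) with no reaction entry: %s",
                            paste(no_rxn, collapse = ", ")))
  }

  age <- db$reports$patient_age
  if (!is.numeric(age)) {
    abort_validation("patient_age must be numeric (years); use NA when absent")
  }
  bad_age <- !is.na(age) & (age < 0 | age > 120)
  if (any(bad_age)) {
    abort_validation(sprintf(
      "patient_age outside [0, 120] for report_id(s): %s",
      paste(ids[bad_age], collapse = ", ")))
  }
  assert_enum(db$reports$reporter_profession, REPORTER_PROFESSIONS,
              "reporter_profession", ids)
  assert_enum(db$reports$reporter_setting, REPORTER_SETTINGS,
              "reporter_setting", ids)
  assert_enum(db$reports$patient_sex, PATIENT_SEXES, "patient_sex", ids)
  if (!is.logical(db$reports$serious)) {
    abort_validation("serious must be logical")
  }
  assert_enum(db$drugs$role, DRUG_ROLES, "drug role", db$drugs$report_id)
  bad_atc <- !is_valid_atc(db$drugs$atc_code)
  if (any(bad_atc)) {
    abort_validation(sprintf("malformed atc_code(s): %s (report_id: %s)",
      paste(unique(db$drugs$atc_code[bad_atc]), collapse = ", "),
      paste(unique(db$drugs$report_id[bad_atc]), collapse = ", ")))
  }
  assert_enum(db$reactions$outcome, REACTION_OUTCOMES, "outcome",
              db$reactions$report_id)
  if (!is.list(db$reactions$seriousness_criteria)) {
    abort_validation("seriousness_criteria must be a list-column of character vectors")
  }
  crit_flat <- unlist(db$reactions$seriousness_criteria, use.names = FALSE)
  assert_enum(crit_flat %||% character(), SERIOUSNESS_CRITERIA,
              "seriousness criterion")
  has_fatal_crit <- vapply(db$reactions$seriousness_criteria,
                           function(cr) "fatal" %in% cr, logical(1))
  bad_fatal <- db$reactions$outcome == "fatal" & !has_fatal_crit
  if (any(bad_fatal)) {
    abort_validation(sprintf(
      "fatal outcome without fatal seriousness criterion: %s",
      paste(unique(db$reactions$report_id[bad_fatal]), collapse = ", ")))
  }
  for (dim in names(CAUSALITY_LEVELS)) {
    assert_enum(db$causality[[dim]], CAUSALITY_LEVELS[[dim]], dim,
                db$causality$report_id)
  }

  mism <- serious_flag_mismatches(db)
  if (length(mism) > 0) {
    abort_validation(sprintf(
      "report-level serious flag inconsistent with reaction criteria for: %s",
      paste(mism, collapse = ", ")))
  }
  invisible(db)
}

#' Report ids whose stored serious flag disagrees with the derived one
#'
#' The report-level serious flag is stored explicitly and also derivable:
#' a report is serious iff any of its reactions carries any seriousness
#' criterion (including `medically_significant`). This consistency checker
#' returns the ids where the two disagree.
#'
#' @param db A [report_db()] object (not necessarily validated).
#' @return Character vector of report ids, empty when consistent.
#' @export
serious_flag_mismatches <- function(db) {
  has_crit <- vapply(db$reactions$seriousness_criteria, length, integer(1)) > 0
  derived <- tapply(has_crit, db$reactions$report_id, any)
  stored <- setNames(db$reports$serious, db$reports$report_id)
  common <- intersect(names(derived), names(stored))
  common[as.logical(derived[common]) != as.logical(stored[common])]
}

#' @export
print.report_db <- function(x, ...) {
  cat(sprintf(
    "<report_db> %d reports | %d drug entries | %d reaction entries | %d causality assessments\n",
    nrow(x$reports), nrow(x$drugs), nrow(x$reactions), nrow(x$causality)))
  invisible(x)
}

#' Number of reports in a database
#' @param db A [report_db()] object.
#' @return Integer count of reports.
#' @export
n_reports <- function(db) nrow(db$reports)

#' Subset a report database by report id
#'
#' Keeps the given reports together with their drug, reaction and causality
#' rows, preserving relational integrity.
#'
#' @param db A [report_db()] object.
#' @param report_ids Character vector of ids to keep.
#' @return A `report_db` restricted to `report_ids`.
#' @export
filter_reports <- function(db, report_ids) {
  report_db(
    reports = dplyr::filter(db$reports, .data$report_id %in% report_ids),
    drugs = dplyr::filter(db$drugs, .data$report_id %in% report_ids),
    reactions = dplyr::filter(db$reactions, .data$report_id %in% report_ids),
    causality = dplyr::filter(db$causality, .data$report_id %in% report_ids),
    validate = FALSE
  )
}
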