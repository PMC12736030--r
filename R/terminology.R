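# Minimal MedDRA-like terminology: a single primary PT -> HLT -> SOC path per
# preferred term, plus named SMQ term sets with narrow/broad scope. Real
# MedDRA is licensed and multi-axial; this package models only what case
# selection and the descriptive tables need, and ships a mock dictionary
# (inst/extdata/mock_meddra.tsv) covering the hostility/aggression query.

ATC_REGEX <- "^[A-Z](\\d{2}([A-Z]([A-Z](\\d{2})?)?)?)?$"
ATC_LEVEL_WIDTHS <- c(1L, 3L, 4L, 5L, 7L)

is_valid_atc <- function(code) {
  !is.na(code) & grepl(ATC_REGEX, code)
}

#' Truncate an ATC code to a classification level
#'
#' The Anatomical Therapeutic Chemical classification has five levels with
#' code prefix lengths 1, 3, 4, 5 and 7 characters: anatomical main group,
#' therapeutic subgroup, pharmacological subgroup, chemical subgroup and
#' chemical substance.
#'
#' @param atc_code Character vector of ATC codes (level-5 or a valid shorter
#'   prefix), e.g. `"N03AX14"`.
#' @param level Integer 1 to 5.
#' @return Character vector of truncated codes.
#' @examples
#' atc_level("N03AX14", 1) # "N"   nervous system
#' atc_level("R03DC03", 2) # "R03" agents against obstructive airway diseases
#' @export
atc_level <- function(atc_code, level) {
  if (length(level) != 1 || !(level %in% 1:5)) {
    abort_validation("level must be a single integer in 1..5")
  }
  bad <- !is_valid_atc(atc_code)
  if (any(bad)) {
    abort_validation(sprintf("malformed ATC code(s): %s",
                             paste(unique(atc_code[bad]), collapse = ", ")))
  }
  width <- ATC_LEVEL_WIDTHS[level]
  short <- nchar(atc_code) < width
  if (any(short)) {
    abort_validation(sprintf(
      "ATC code(s) %s do not reach level %d (need %d characters)",
      paste(unique(atc_code[short]), collapse = ", "), level, width))
  }
  substr(atc_code, 1L, width)
}

#' Load a PT/HLT/SOC terminology with SMQ memberships
#'
#' Reads a tab-separated dictionary with columns `pt_code`, `pt_name`,
#' `hlt_code`, `hlt_name`, `soc_code`, `soc_name` and `smq_memberships`
#' (semicolon-separated `smq_name:scope` tokens, scope `narrow` or `broad`;
#' empty when the PT belongs to no SMQ). Each PT maps to exactly one HLT and
#' one SOC (the primary path).
#'
#' @param path Dictionary file; defaults to the bundled mock dictionary,
#'   which covers the hostility/aggression SMQ (narrow plus sensitive terms)
#'   and a set of background PTs.
#' @return A `term_dictionary`: list with `pt_records` (tibble), `hlt_names`,
#'   `soc_names` (named character vectors) and `smq_sets` (per SMQ, character
#'   vectors `narrow` and `broad_extra` of PT codes).
#' @export
load_dictionary <- function(path = mock_dictionary_path()) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE)
  need <- c("pt_code", "pt_name", "hlt_code", "hlt_name",
            "soc_code", "soc_name", "smq_memberships")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    abort_schema(sprintf("dictionary is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  incomplete <- tab$hlt_code == "" | tab$soc_code == ""
  if (any(incomplete)) {
    abort_schema(sprintf("PT(s) with missing HLT/SOC: %s",
                         paste(tab$pt_code[incomplete], collapse = ", ")))
  }
  if (anyDuplicated(tab$pt_code)) {
    abort_schema("duplicate pt_code rows; each PT has one primary path")
  }

  smq_sets <- list()
  for (i in seq_len(nrow(tab))) {
    memb <- tab$smq_memberships[i]
    if (memb == "") next
    for (token in strsplit(memb, ";", fixed = TRUE)[[1]]) {
      parts <- strsplit(token, ":", fixed = TRUE)[[1]]
      if (length(parts) != 2 || !(parts[2] %in% c("narrow", "broad"))) {
        abort_schema(sprintf("bad smq membership token '%s' on PT %s",
                             token, tab$pt_code[i]))
      }
      smq <- parts[1]
      if (is.null(smq_sets[[smq]])) {
        smq_sets[[smq]] <- list(narrow = character(), broad_extra = character())
      }
      slot <- if (parts[2] == "narrow") "narrow" else "broad_extra"
      smq_sets[[smq]][[slot]] <- c(smq_sets[[smq]][[slot]], tab$pt_code[i])
    }
  }

  structure(
    list(
      pt_records = tibble::tibble(
        pt_code = tab$pt_code,
        pt_name = tab$pt_name,
        hlt_code = tab$hlt_code,
        soc_code = tab$soc_code
      ),
      hlt_names = setNames(tab$hlt_name, tab$hlt_code)[!duplicated(tab$hlt_code)],
      soc_names = setNames(tab$soc_name, tab$soc_code)[!duplicated(tab$soc_code)],
      smq_sets = smq_sets
    ),
    class = "term_dictionary"
  )
}

#' Path to the bundled mock dictionary
#' @return File path of the packaged `mock_meddra.tsv`.
#' @export
mock_dictionary_path <- function() {
  system.file("extdata", "mock_meddra.tsv", package = "vigicase", mustWork = TRUE)
}

#' @export
print.term_dictionary <- function(x, ...) {
  cat(sprintf("<term_dictionary> %d PTs | %d HLTs | %d SOCs | SMQs: %s\n",
              nrow(x$pt_records), length(x$hlt_names), length(x$soc_names),
              paste(names(x$smq_sets), collapse = ", ")))
  invisible(x)
}

#' Resolve PT codes by (case-insensitive) preferred-term name
#'
#' @param dictionary A `term_dictionary`.
#' @param pt_names Character vector of PT names; matching normalizes case and
#'   surrounding whitespace.
#' @return Character vector of PT codes (NA where unmatched).
#' @export
pt_code_for_name <- function(dictionary, pt_names) {
  norm <- function(x) tolower(trimws(x))
  dictionary$pt_records$pt_code[
    match(norm(pt_names), norm(dictionary$pt_records$pt_name))]
}

#' PT codes of an SMQ at a given scope
#'
#' Narrow scope favours specificity; broad scope is the union of the narrow
#' set and the additional sensitive terms.
#'
#' @param dictionary A `term_dictionary`.
#' @param smq_name Name of the SMQ, e.g. `"hostility_aggression"`.
#' @param scope `"narrow"` or `"broad"`.
#' @return Character vector of PT codes.
#' @export
smq_terms <- function(dictionary, smq_name, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  set <- dictionary$smq_sets[[smq_name]]
  if (is.null(set)) {
    abort(sprintf("unknown SMQ '%s'; available: %s", smq_name,
                  paste(names(dictionary$smq_sets), collapse = ", ")),
          class = "vigicase_lookup_error")
  }
  if (scope == "narrow") set$narrow else union(set$narrow, set$broad_extra)
}

#' Select case reports by SMQ membership
#'
#' Implements the case/non-case partition: a report is a case when at least
#' one of its reactions is coded to a PT in the scoped SMQ term set; all
#' other reports in the database are non-cases. A report with several
#' matching PTs is a single case.
#'
#' @param db A [report_db()].
#' @param dictionary A `term_dictionary`.
#' @param smq_name SMQ to query.
#' @param scope `"narrow"` or `"broad"`.
#' @return A list with `cases` (a `report_db` of the case reports),
#'   `case_ids` (character), and `non_case_count`
#'   (`n_reports(db) - length(case_ids)`).
#' @export
select_cases <- function(db, dictionary, smq_name, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  terms <- smq_terms(dictionary, smq_name, scope)
  case_ids <- unique(db$reactions$report_id[db$reactions$pt_code %in% terms])
  # preserve database report order
  case_ids <- db$reports$report_id[db$reports$report_id %in% case_ids]
  list(
    cases = filter_reports(db, case_ids),
    case_ids = case_ids,
    non_case_count = n_reports(db) - length(case_ids)
  )
}
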