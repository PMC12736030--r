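# On-disk schemas
#
# csv_bundle: a directory holding reports.csv, drugs.csv, reactions.csv and
# (optionally) causality.csv, keyed by report_id. Multi-valued seriousness
# criteria are semicolon-joined in reactions.csv; an empty field means no
# criterion. Absent age is the explicit token NA, never an empty string.
#
# json_lines: one JSON object per line with the drug and reaction lists
# nested inline; absent optional fields are JSON null.

CSV_COLUMNS <- list(
  reports = c("report_id", "received_date", "reporter_profession",
              "reporter_setting", "patient_age", "patient_sex", "serious"),
  drugs = c("report_id", "drug_name", "atc_code", "role"),
  reactions = c("report_id", "pt_code", "seriousness_criteria", "outcome"),
  causality = c("report_id", "time_sequence", "prior_knowledge",
                "dechallenge", "rechallenge", "alternative_cause")
)

#' Read spontaneous reports from disk
#'
#' @param path Directory of the csv bundle, or the `.jsonl` file path.
#' @param format `"csv_bundle"` (three or four normalized CSV tables) or
#'   `"json_lines"` (one nested report object per line).
#' @return A validated [report_db()].
#' @seealso [write_reports()] for the inverse; the pair round-trips
#'   losslessly.
#' @export
read_reports <- function(path, format = c("csv_bundle", "json_lines")) {
  format <- match.arg(format)
  db <- switch(format,
    csv_bundle = read_csv_bundle(path),
    json_lines = read_json_lines(path)
  )
  validate_report_db(db)
  db
}

#' Write spontaneous reports to disk
#'
#' @param db A validated [report_db()].
#' @param path Target directory (`csv_bundle`) or file path (`json_lines`).
#' @inheritParams read_reports
#' @return `path`, invisibly.
#' @export
write_reports <- function(db, path, format = c("csv_bundle", "json_lines")) {
  format <- match.arg(format)
  validate_report_db(db)
  switch(format,
    csv_bundle = write_csv_bundle(db, path),
    json_lines = write_json_lines(db, path)
  )
  invisible(path)
}

# csv bundle -----------------------------------------------------------------

read_csv_bundle <- function(path) {
  if (!dir.exists(path)) abort_schema(sprintf("no such bundle directory: %s", path))
  read_one <- function(name, required) {
    file <- file.path(path, paste0(name, ".csv"))
    if (!file.exists(file)) {
      if (required) abort_schema(sprintf("bundle is missing %s.csv", name))
      return(NULL)
    }
    tab <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()),
                           na = character(), progress = FALSE)
    missing <- setdiff(CSV_COLUMNS[[name]], names(tab))
    if (length(missing) > 0) {
      abort_schema(sprintf("%s.csv is missing column(s): %s",
                           name, paste(missing, collapse = ", ")))
    }
    tab
  }
  reports <- read_one("reports", required = TRUE)
  drugs <- read_one("drugs", required = TRUE)
  reactions <- read_one("reactions", required = TRUE)
  causality <- read_one("causality", required = FALSE)

  age <- parse_age(reports$patient_age, reports$report_id)
  reports <- tibble::tibble(
    report_id = reports$report_id,
    received_date = as.Date(reports$received_date),
    reporter_profession = reports$reporter_profession,
    reporter_setting = reports$reporter_setting,
    patient_age = age,
    patient_sex = reports$patient_sex,
    serious = parse_logical(reports$serious, reports$report_id)
  )
  reactions <- tibble::tibble(
    report_id = reactions$report_id,
    pt_code = reactions$pt_code,
    seriousness_criteria = split_criteria(reactions$seriousness_criteria),
    outcome = reactions$outcome
  )
  report_db(reports, drugs[CSV_COLUMNS$drugs], reactions,
            causality = if (!is.null(causality)) causality[CSV_COLUMNS$causality],
            validate = FALSE)
}

write_csv_bundle <- function(db, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  reports_out <- dplyr::mutate(
    db$reports,
    received_date = format(.data$received_date, "%Y-%m-%d"),
    patient_age = ifelse(is.na(.data$patient_age), "NA",
                         format(.data$patient_age, trim = TRUE)),
    serious = ifelse(.data$serious, "TRUE", "FALSE")
  )
  reactions_out <- dplyr::mutate(
    db$reactions,
    seriousness_criteria = vapply(.data$seriousness_criteria,
                                  paste, character(1), collapse = ";")
  )
  readr::write_csv(reports_out, file.path(path, "reports.csv"), progress = FALSE)
  readr::write_csv(db$drugs, file.path(path, "drugs.csv"), progress = FALSE)
  readr::write_csv(reactions_out, file.path(path, "reactions.csv"), progress = FALSE)
  if (nrow(db$causality) > 0) {
    readr::write_csv(db$causality, file.path(path, "causality.csv"), progress = FALSE)
  }
  invisible(path)
}

parse_age <- function(x, ids) {
  out <- rep(NA_real_, length(x))
  present <- !(x %in% c("NA", ""))
  suppressWarnings(val <- as.numeric(x[present]))
  bad <- is.na(val)
  if (any(bad)) {
    abort_validation(sprintf(
      "non-numeric patient_age %s for report_id(s): %s",
      paste(sQuote(x[present][bad]), collapse = ", "),
      paste(ids[present][bad], collapse = ", ")))
  }
  out[present] <- val
  out
}

parse_logical <- function(x, ids) {
  up <- toupper(x)
  bad <- !(up %in% c("TRUE", "FALSE"))
  if (any(bad)) {
    abort_validation(sprintf("non-boolean serious value for report_id(s): %s",
                             paste(ids[bad], collapse = ", ")))
  }
  up == "TRUE"
}

split_criteria <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

# json lines -----------------------------------------------------------------

read_json_lines <- function(path) {
  if (!file.exists(path)) abort_schema(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)

  null_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  reports <- purrr::map_dfr(recs, function(r) {
    tibble::tibble(
      report_id = as.character(r$report_id),
      received_date = as.Date(r$received_date),
      reporter_profession = null_chr(r$reporter_profession),
      reporter_setting = null_chr(r$reporter_setting),
      patient_age = if (is.null(r$patient_age)) NA_real_ else as.numeric(r$patient_age),
      patient_sex = null_chr(r$patient_sex),
      serious = as.logical(r$serious)
    )
  })
  drugs <- purrr::map_dfr(recs, function(r) {
    purrr::map_dfr(r$drugs, function(d) tibble::tibble(
      report_id = as.character(r$report_id),
      drug_name = as.character(d$drug_name),
      atc_code = as.character(d$atc_code),
      role = as.character(d$role)
    ))
  })
  reactions <- purrr::map_dfr(recs, function(r) {
    purrr::map_dfr(r$reactions, function(rx) tibble::tibble(
      report_id = as.character(r$report_id),
      pt_code = as.character(rx$pt_code),
      seriousness_criteria = list(as.character(unlist(rx$seriousness_criteria))),
      outcome = as.character(rx$outcome)
    ))
  })
  causality <- purrr::map_dfr(recs, function(r) {
    if (is.null(r$causality)) return(NULL)
    c_ <- r$causality
    tibble::tibble(
      report_id = as.character(r$report_id),
      time_sequence = null_chr(c_$time_sequence),
      prior_knowledge = null_chr(c_$prior_knowledge),
      dechallenge = null_chr(c_$dechallenge),
      rechallenge = null_chr(c_$rechallenge),
      alternative_cause = null_chr(c_$alternative_cause)
    )
  })
  if (nrow(reports) == 0) {
    return(report_db(empty_reports_tbl(), empty_drugs_tbl(),
                     empty_reactions_tbl(), validate = FALSE))
  }
  report_db(reports, drugs, reactions,
            causality = if (nrow(causality) > 0) causality,
            validate = FALSE)
}

write_json_lines <- function(db, path) {
  caus_idx <- match(db$reports$report_id, db$causality$report_id)
  drug_split <- split(db$drugs, factor(db$drugs$report_id,
                                       levels = db$reports$report_id))
  rxn_split <- split(db$reactions, factor(db$reactions$report_id,
                                          levels = db$reports$report_id))
  lines <- vapply(seq_len(nrow(db$reports)), function(i) {
    rep_row <- db$reports[i, ]
    dr <- drug_split[[rep_row$report_id]]
    rx <- rxn_split[[rep_row$report_id]]
    obj <- list(
      report_id = rep_row$report_id,
      received_date = format(rep_row$received_date, "%Y-%m-%d"),
      reporter_profession = rep_row$reporter_profession,
      reporter_setting = rep_row$reporter_setting,
      patient_age = if (is.na(rep_row$patient_age)) NULL else rep_row$patient_age,
      patient_sex = rep_row$patient_sex,
      serious = rep_row$serious,
      drugs = lapply(seq_len(nrow(dr)), function(j) list(
        drug_name = dr$drug_name[j], atc_code = dr$atc_code[j], role = dr$role[j]
      )),
      reactions = lapply(seq_len(nrow(rx)), function(j) list(
        pt_code = rx$pt_code[j],
        seriousness_criteria = as.list(rx$seriousness_criteria[[j]]),
        outcome = rx$outcome[j]
      )),
      causality = if (is.na(caus_idx[i])) NULL else {
        cc <- db$causality[caus_idx[i], ]
        list(
          time_sequence = cc$time_sequence,
          prior_knowledge = cc$prior_knowledge,
          dechallenge = cc$dechallenge,
          rechallenge = cc$rechallenge,
          alternative_cause = cc$alternative_cause
        )
      }
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

empty_reports_tbl <- function() {
  tibble::tibble(
    report_id = character(), received_date = as.Date(character()),
    reporter_profession = character(), reporter_setting = character(),
    patient_age = numeric(), patient_sex = character(), serious = logical()
  )
}

empty_drugs_tbl <- function() {
  tibble::tibble(report_id = character(), drug_name = character(),
                 atc_code = character(), role = character())
}

empty_reactions_tbl <- function() {
  tibble::tibble(report_id = character(), pt_code = character(),
                 seriousness_criteria = list(), outcome = character())
}
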