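AGE_GROUPS <- c("infant", "child", "adolescent", "adult", "elderly", "unknown")

#' Assign ages to the study's age groups
#'
#' Bins: infant \[0, 2), child \[2, 12), adolescent \[12, 18), adult
#' \[18, 65\], elderly (65, Inf). Bins are lower-inclusive; 65 is adult and
#' over 65 elderly. An absent age maps to `unknown`.
#'
#' @param age Numeric vector of ages in years; `NA` allowed.
#' @return Factor with levels infant, child, adolescent, adult, elderly,
#'   unknown.
#' @examples
#' assign_age_group(c(1.5, 12, 70, NA))
#' @export
assign_age_group <- function(age) {
  if (any(!is.na(age) & age < 0)) {
    abort_validation("age must be non-negative")
  }
  out <- rep("unknown", length(age))
  ok <- !is.na(age)
  out[ok & age < 2] <- "infant"
  out[ok & age >= 2 & age < 12] <- "child"
  out[ok & age >= 12 & age < 18] <- "adolescent"
  out[ok & age >= 18 & age <= 65] <- "adult"
  out[ok & age > 65] <- "elderly"
  factor(out, levels = AGE_GROUPS)
}

#' Construct a frequency table
#'
#' A `freq_table` is a tibble of `(key, count, percentage)` rows carrying its
#' denominator and the unit being counted (`reports`, `reactions` or
#' `drug_entries`) as attributes, so report-level and reaction-level tallies
#' cannot be silently mixed. Percentages are rounded half-up.
#'
#' @param counts Named integer vector (names become `key`).
#' @param denominator Denominator for the percentages.
#' @param kind One of `"reports"`, `"reactions"`, `"drug_entries"`.
#' @param digits Decimal places for percentages (default 1).
#' @param sort Sort rows by descending count, ties broken by key (default
#'   `TRUE`; `FALSE` keeps the input order, e.g. a fixed enum order).
#' @return A `freq_table` tibble.
#' @export
freq_table <- function(counts, denominator = sum(counts),
                       kind = c("reports", "reactions", "drug_entries"),
                       digits = 1, sort = TRUE) {
  kind <- match.arg(kind)
  tab <- tibble::tibble(
    key = names(counts) %||% as.character(seq_along(counts)),
    count = as.integer(counts),
    percentage = if (denominator > 0) {
      round_half_up(100 * as.integer(counts) / denominator, digits)
    } else {
      rep(NA_real_, length(counts))
    }
  )
  if (sort) {
    tab <- dplyr::arrange(tab, dplyr::desc(.data$count), .data$key)
  }
  structure(tab, denominator = denominator, denominator_kind = kind,
            class = c("freq_table", class(tab)))
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("# denominator: %d %s\n",
              attr(x, "denominator"), attr(x, "denominator_kind")))
  NextMethod()
}

#' Write a frequency table as CSV
#'
#' Prepends a comment line naming the denominator and its kind.
#'
#' @param tab A [freq_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(tab, path) {
  writeLines(sprintf("# denominator=%d kind=%s",
                     attr(tab, "denominator"), attr(tab, "denominator_kind")),
             path)
  readr::write_csv(tibble::as_tibble(tab), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

case_reaction_rows <- function(cases, dictionary, smq_name, scope) {
  terms <- smq_terms(dictionary, smq_name, scope)
  dplyr::filter(cases$reactions, .data$pt_code %in% terms)
}

#' Tabulate case reactions by preferred term
#'
#' Counts the event-matching reaction entries across case reports, one row
#' per PT, as a reaction-level frequency table (several reactions may be
#' reported in one report, so the denominator exceeds the case count).
#'
#' @param cases A `report_db` of case reports (from [select_cases()]).
#' @param dictionary A `term_dictionary`.
#' @param smq_name,scope The SMQ and scope that defined the cases.
#' @return A [freq_table()] keyed by PT name, `denominator_kind =
#'   "reactions"`.
#' @export
tabulate_reactions_by_pt <- function(cases, dictionary,
                                     smq_name = "hostility_aggression",
                                     scope = "narrow") {
  rxn <- case_reaction_rows(cases, dictionary, smq_name, scope)
  name <- dictionary$pt_records$pt_name[
    match(rxn$pt_code, dictionary$pt_records$pt_code)]
  freq_table(table(name), kind = "reactions")
}

#' Tabulate reaction outcomes
#'
#' Outcome of each event-matching reaction entry (recovered, recovering, not
#' recovered, recovered with sequelae, fatal, not reported), reaction-level
#' denominator.
#'
#' @inheritParams tabulate_reactions_by_pt
#' @return A [freq_table()] over the outcome categories.
#' @export
tabulate_outcomes <- function(cases, dictionary,
                              smq_name = "hostility_aggression",
                              scope = "narrow") {
  rxn <- case_reaction_rows(cases, dictionary, smq_name, scope)
  counts <- table(factor(rxn$outcome, levels = REACTION_OUTCOMES))
  freq_table(counts, kind = "reactions", sort = FALSE)
}

#' Tabulate suspected drugs among cases
#'
#' Counts drug entries with a suspected role across the case reports, at an
#' ATC level or by active substance. The denominator is the total number of
#' suspected drug entries (a report may carry several). Rows are sorted by
#' descending count, ties broken alphabetically.
#'
#' @param cases A `report_db` of case reports.
#' @param level `"substance"` or an ATC level 1 to 5.
#' @param roles Drug roles counted as suspected; the default includes
#'   interaction entries alongside plain suspects.
#' @return A [freq_table()] with `denominator_kind = "drug_entries"`.
#' @export
tabulate_drugs <- function(cases, level = "substance",
                           roles = c("suspect", "interaction")) {
  drugs <- dplyr::filter(cases$drugs, .data$role %in% roles)
  key <- if (identical(level, "substance")) {
    drugs$drug_name
  } else {
    atc_level(drugs$atc_code, as.integer(level))
  }
  freq_table(table(key), kind = "drug_entries")
}

#' Demographic and reporting-profile tabulations
#'
#' Report-level descriptive tables: age-group distribution, sex within each
#' age group (each group's case count as denominator), reporter profession,
#' reporter setting, profession crossed with setting, and the count of
#' reports per calendar year of receipt.
#'
#' @param cases A `report_db` of case reports.
#' @return A list with elements `age_group`, `sex_by_age_group` (tibble with
#'   per-group percentages), `reporter_profession`, `reporter_setting`,
#'   `profession_by_setting` (tibble), and `year` (tibble of per-year
#'   counts).
#' @export
tabulate_demographics <- function(cases) {
  rep_tbl <- dplyr::mutate(cases$reports,
                           age_group = assign_age_group(.data$patient_age))
  age_group <- freq_table(table(rep_tbl$age_group), kind = "reports",
                          sort = FALSE)
  sex_by_age_group <- rep_tbl |>
    dplyr::count(.data$age_group, .data$patient_sex, .drop = FALSE) |>
    dplyr::group_by(.data$age_group) |>
    dplyr::mutate(
      group_total = sum(.data$n),
      percentage = ifelse(.data$group_total > 0,
                          round_half_up(100 * .data$n / .data$group_total, 1),
                          NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::rename(sex = "patient_sex", count = "n")
  profession <- freq_table(
    table(factor(rep_tbl$reporter_profession, levels = REPORTER_PROFESSIONS)),
    kind = "reports", sort = FALSE)
  setting <- freq_table(
    table(factor(rep_tbl$reporter_setting, levels = REPORTER_SETTINGS)),
    kind = "reports", sort = FALSE)
  profession_by_setting <- rep_tbl |>
    dplyr::count(.data$reporter_profession, .data$reporter_setting) |>
    dplyr::group_by(.data$reporter_profession) |>
    dplyr::mutate(percentage = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup() |>
    dplyr::rename(count = "n")
  year <- rep_tbl |>
    dplyr::mutate(year = as.integer(format(.data$received_date, "%Y"))) |>
    dplyr::count(.data$year, name = "count")
  list(
    age_group = age_group,
    sex_by_age_group = sex_by_age_group,
    reporter_profession = profession,
    reporter_setting = setting,
    profession_by_setting = profession_by_setting,
    year = year
  )
}
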