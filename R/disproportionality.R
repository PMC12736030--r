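# Case/non-case disproportionality. Cases are the reports containing the
# event of interest; non-cases are all other reports in the same database.
# For a given drug the 2x2 table is
#
#               event      no event
#   drug          a            b
#   no drug       c            d
#
# counted at REPORT level: a report contributes once per cell, however many
# matching reactions or drug entries it carries. Exposure means the drug
# appears with a suspected role (suspect, and by default also interaction).

#' 2x2 contingency table for a drug-event pair
#'
#' @param a Reports with the drug and the event.
#' @param b Reports with the drug, without the event.
#' @param c Reports with the event, without the drug.
#' @param d Reports with neither.
#' @param derived Marks a table produced by [complete_table()]; such tables
#'   may have non-integer cells and serve verification only, never as data.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, derived = FALSE) {
  cells <- unname(c(a, b, c, d))
  if (any(is.na(cells)) || any(cells < 0)) {
    abort_validation("contingency cells must be non-negative and non-missing")
  }
  if (!derived && any(cells != trunc(cells))) {
    abort_validation("non-integer cells are only allowed in derived tables")
  }
  structure(list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
                 derived = derived),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table%s> a=%g b=%g c=%g d=%g (N=%g)\n",
              if (x$derived) ", derived" else "", x$a, x$b, x$c, x$d,
              x$a + x$b + x$c + x$d))
  invisible(x)
}

#' Signal-detection thresholds
#'
#' The conventional criteria used for spontaneous-report screening: at least
#' `min_reports` case reports of the drug, lower 95% confidence bound of the
#' ROR above 1, PRR above 2, and Yates-corrected chi-square above 4. All
#' inequalities are strict.
#'
#' @param min_reports Minimum number of case reports mentioning the drug
#'   (default 3).
#' @param z Normal quantile for the confidence level (default 1.96, i.e.
#'   two-sided 95%; fixed rather than recomputed for bit-stable intervals).
#' @param ror_ci_low_min,prr_min,chi2_min Cut-offs (defaults 1, 2, 4).
#' @param zero_cell_correction `"haldane_0.5"` (add 0.5 to every cell when
#'   any cell is zero; the default) or `"none"` (zero cells give an
#'   undefined, `NA`, estimate).
#' @return A `signal_thresholds` list.
#' @export
signal_thresholds <- function(min_reports = 3, z = 1.96, ror_ci_low_min = 1,
                              prr_min = 2, chi2_min = 4,
                              zero_cell_correction = c("haldane_0.5", "none")) {
  zero_cell_correction <- match.arg(zero_cell_correction)
  stopifnot(min_reports > 0, z > 0, ror_ci_low_min > 0, prr_min > 0,
            chi2_min > 0)
  structure(
    list(min_reports = min_reports, z = z, ror_ci_low_min = ror_ci_low_min,
         prr_min = prr_min, chi2_min = chi2_min,
         zero_cell_correction = zero_cell_correction),
    class = "signal_thresholds")
}

#' Build the drug-event 2x2 table from a report database
#'
#' @param db A [report_db()].
#' @param dictionary A `term_dictionary`.
#' @param smq_name,scope SMQ defining the event (see [select_cases()]).
#' @param drug_name Active-substance name; a drug absent from the database
#'   yields a = b = 0 (an empty-exposure table, not an error).
#' @param roles Drug roles counted as exposure (default suspect +
#'   interaction).
#' @return A `contingency_table` whose cells sum to `n_reports(db)`.
#' @export
build_table <- function(db, dictionary, smq_name, scope, drug_name,
                        roles = c("suspect", "interaction")) {
  sel <- select_cases(db, dictionary, smq_name, scope)
  exposed_ids <- unique(db$drugs$report_id[
    db$drugs$drug_name == drug_name & db$drugs$role %in% roles])
  is_case <- db$reports$report_id %in% sel$case_ids
  is_exposed <- db$reports$report_id %in% exposed_ids
  contingency_table(
    a = sum(is_case & is_exposed),
    b = sum(!is_case & is_exposed),
    c = sum(is_case & !is_exposed),
    d = sum(!is_case & !is_exposed)
  )
}

apply_zero_cell <- function(table, thresholds) {
  cells <- c(table$a, table$b, table$c, table$d)
  if (all(cells > 0)) {
    return(list(cells = cells, corrected = FALSE, defined = TRUE))
  }
  if (thresholds$zero_cell_correction == "haldane_0.5") {
    list(cells = cells + 0.5, corrected = TRUE, defined = TRUE)
  } else {
    list(cells = cells, corrected = FALSE, defined = FALSE)
  }
}

#' Reporting odds ratio with Wald confidence interval
#'
#' ROR = (a d) / (b c); the CI is
#' exp(log ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d)).
#'
#' @param table A `contingency_table`.
#' @param thresholds A [signal_thresholds()]; supplies `z` and the zero-cell
#'   policy.
#' @return List with `estimate`, `ci` (low, high), and `corrected` (whether
#'   the zero-cell correction was applied). With a zero cell and correction
#'   `"none"`, `estimate` and `ci` are `NA` (an explicitly undefined result,
#'   not a silent infinity).
#' @export
compute_ror <- function(table, thresholds = signal_thresholds()) {
  zc <- apply_zero_cell(table, thresholds)
  if (!zc$defined) {
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                corrected = FALSE))
  }
  a <- zc$cells[1]; b <- zc$cells[2]; c <- zc$cells[3]; d <- zc$cells[4]
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(est) + c(-1, 1) * thresholds$z * se)
  list(estimate = est, ci = ci, corrected = zc$corrected)
}

#' Proportional reporting ratio with Wald confidence interval
#'
#' PRR = \[a / (a + b)\] / \[c / (c + d)\]; the CI is
#' exp(log PRR +/- z sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))).
#'
#' @inheritParams compute_ror
#' @return As [compute_ror()].
#' @export
compute_prr <- function(table, thresholds = signal_thresholds()) {
  zc <- apply_zero_cell(table, thresholds)
  if (!zc$defined) {
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                corrected = FALSE))
  }
  a <- zc$cells[1]; b <- zc$cells[2]; c <- zc$cells[3]; d <- zc$cells[4]
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  ci <- exp(log(est) + c(-1, 1) * thresholds$z * se)
  list(estimate = est, ci = ci, corrected = zc$corrected)
}

#' Yates continuity-corrected chi-square statistic for a 2x2 table
#'
#' N (|ad - bc| - N/2)^2 / \[(a+b)(c+d)(a+c)(b+d)\] with N the table total,
#' clamped to 0 when the correction exceeds |ad - bc| (so a proportional
#' table gives exactly 0).
#'
#' @param table A `contingency_table` with all margins positive.
#' @return The statistic (>= 0), or `NA` when a margin is zero (undefined).
#' @export
compute_chi2_yates <- function(table) {
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    return(NA_real_)
  }
  dev <- abs(a * d - b * c)
  if (dev <= n / 2) {
    return(0)
  }
  n * (dev - n / 2)^2 / prod(margins)
}

#' Evaluate the signal criteria
#'
#' @param n Number of case reports with the drug (cell a).
#' @param ror_ci_low Lower ROR confidence bound.
#' @param prr PRR point estimate.
#' @param chi2 Yates-corrected chi-square.
#' @param thresholds A [signal_thresholds()].
#' @return List with `signal` (all four criteria met; strict inequalities)
#'   and `criteria_met`, the subset of `min_reports`, `ror_ci_low_gt_1`,
#'   `prr_gt_2`, `chi2_gt_4` that hold. `NA` statistics fail their
#'   criterion.
#' @export
evaluate_signal <- function(n, ror_ci_low, prr, chi2,
                            thresholds = signal_thresholds()) {
  met <- c(
    min_reports = n >= thresholds$min_reports,
    ror_ci_low_gt_1 = isTRUE(ror_ci_low > thresholds$ror_ci_low_min),
    prr_gt_2 = isTRUE(prr > thresholds$prr_min),
    chi2_gt_4 = isTRUE(chi2 > thresholds$chi2_min)
  )
  list(signal = all(met), criteria_met = names(met)[met])
}

#' Screen every drug in a database for disproportionate reporting
#'
#' Runs the full case/non-case analysis: selects cases by SMQ, then for each
#' drug with at least `min_reports` suspected mentions among the cases
#' builds the 2x2 table and computes ROR, PRR, Yates chi-square and the
#' signal flags. Results are ordered by ATC code then descending ROR
#' (deterministically; name breaks remaining ties).
#'
#' @inheritParams build_table
#' @param thresholds A [signal_thresholds()].
#' @return Tibble with one row per screened drug: `drug_name`, `atc_code`,
#'   `n`, `a`, `b`, `c`, `d`, `ror`, `ror_low`, `ror_high`, `prr`,
#'   `prr_low`, `prr_high`, `chi2`, `signal`, `criteria_met`
#'   (comma-joined).
#' @export
screen <- function(db, dictionary, smq_name, scope,
                   thresholds = signal_thresholds(),
                   roles = c("suspect", "interaction")) {
  sel <- select_cases(db, dictionary, smq_name, scope)
  n_total <- n_reports(db)
  n_cases <- length(sel$case_ids)
  if (n_cases == 0) {
    return(empty_screen_tbl())
  }

  exposure <- dplyr::filter(db$drugs, .data$role %in% roles) |>
    dplyr::distinct(.data$report_id, .data$drug_name, .keep_all = TRUE)
  is_case_exposure <- exposure$report_id %in% sel$case_ids
  case_n <- table(exposure$drug_name[is_case_exposure])
  candidates <- names(case_n)[case_n >= thresholds$min_reports]
  if (length(candidates) == 0) {
    return(empty_screen_tbl())
  }
  exposed_n <- table(exposure$drug_name)[candidates]
  atc <- exposure$atc_code[match(candidates, exposure$drug_name)]

  rows <- lapply(seq_along(candidates), function(i) {
    a <- as.integer(case_n[candidates[i]])
    ab <- as.integer(exposed_n[i])
    tab <- contingency_table(a = a, b = ab - a, c = n_cases - a,
                             d = n_total - n_cases - (ab - a))
    ror_est <- compute_ror(tab, thresholds)
    prr_est <- compute_prr(tab, thresholds)
    chi2 <- compute_chi2_yates(tab)
    sig <- evaluate_signal(a, ror_est$ci[1], prr_est$estimate, chi2,
                           thresholds)
    tibble::tibble(
      drug_name = candidates[i], atc_code = atc[i],
      n = a, a = a, b = ab - a, c = n_cases - a,
      d = n_total - n_cases - (ab - a),
      ror = ror_est$estimate, ror_low = ror_est$ci[1],
      ror_high = ror_est$ci[2],
      prr = prr_est$estimate, prr_low = prr_est$ci[1],
      prr_high = prr_est$ci[2],
      chi2 = chi2, signal = sig$signal,
      criteria_met = paste(sig$criteria_met, collapse = ",")
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$atc_code, dplyr::desc(.data$ror), .data$drug_name)
}

empty_screen_tbl <- function() {
  tibble::tibble(
    drug_name = character(), atc_code = character(), n = integer(),
    a = integer(), b = integer(), c = integer(), d = integer(),
    ror = numeric(), ror_low = numeric(), ror_high = numeric(),
    prr = numeric(), prr_low = numeric(), prr_high = numeric(),
    chi2 = numeric(), signal = logical(), criteria_met = character()
  )
}

#' Write screening results as CSV
#'
#' Emits both a display set of columns rounded to 2 decimals (mirroring how
#' disproportionality tables are usually printed) and the full-precision
#' values.
#'
#' @param results Tibble from [screen()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(results, path) {
  disp <- dplyr::mutate(results, dplyr::across(
    c("ror", "ror_low", "ror_high", "prr", "prr_low", "prr_high", "chi2"),
    list(display = ~ round_half_up(.x, 2))
  ))
  readr::write_csv(disp, path, progress = FALSE)
  invisible(path)
}

#' Complete a 2x2 table from published summary statistics
#'
#' Disproportionality tables usually print, per drug, the case count `a` and
#' the ROR but not the drug's exposure total, so the full 2x2 table cannot
#' be read off directly. Given the database total, the case total and the
#' printed ROR, the missing cell has the closed form
#' b = a (N - C) / (ROR (C - a) + a), with c = C - a and d = N - C - b.
#' The result lets the printed PRR and ROR confidence bounds be recomputed
#' and audited.
#'
#' @param a Case reports with the drug.
#' @param case_total Total cases C in the database.
#' @param database_total Total reports N.
#' @param ror The reporting odds ratio (a d)/(b c).
#' @return A derived `contingency_table` (cells may be non-integer); it is a
#'   verification device, not data.
#' @examples
#' tab <- complete_table(a = 35, case_total = 533,
#'                       database_total = 353165, ror = 17.85)
#' compute_prr(tab)$estimate # ~17.43
#' @export
complete_table <- function(a, case_total, database_total, ror) {
  if (!(ror > 0)) abort_validation("ror must be positive")
  if (!(a > 0 && a < case_total && case_total < database_total)) {
    abort_validation("need 0 < a < case_total < database_total")
  }
  b <- a * (database_total - case_total) / (ror * (case_total - a) + a)
  d <- database_total - case_total - b
  if (b <= 0 || d < 0) {
    abort("parameters imply an infeasible exposure cell",
          class = "vigicase_infeasibility_error")
  }
  contingency_table(a = a, b = b, c = case_total - a, d = d, derived = TRUE)
}
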