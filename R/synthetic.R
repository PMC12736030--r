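# Seeded generator of synthetic spontaneous-report databases.
#
# Caseness follows a logistic model on drug exposures: a report exposed to
# drugs with effect sizes beta (log reporting odds ratios) is a violence
# case with probability plogis(qlogis(p0) + sum(beta)). For a rare
# background rate p0 the realized ROR of an injected drug is approximately
# exp(beta), which makes the association strength directly controllable.
#
# A single global random stream is used, with this documented draw order:
#   1. per-drug exposure indicators (catalogue order), then whole-row
#      redraws until every report has at least one drug;
#   2. caseness;
#   3. demographics (age group, age within bin, sex);
#   4. reporter profession, then setting;
#   5. receipt year, then day of year;
#   6. reaction counts and PT draws (cases first, then non-cases);
#   7. per-reaction seriousness category, then outcome;
#   8. causality categories (cases only);
#   9. drug-entry roles.
# Adding fields therefore preserves reproducibility only at the same
# config version (tagged in the manifest).

GENERATOR_VERSION <- "vigicase-gen-1"

#' Configuration for the synthetic report generator
#'
#' @param n_reports Number of reports to generate.
#' @param drug_catalogue Tibble with columns `drug_name`, `atc_code`,
#'   `baseline_exposure_prob` (independent per-drug exposure probability)
#'   and `violence_log_ror` (injected effect size; 0 for a null drug).
#' @param background_violence_prob Probability that a report with no
#'   effect-drug exposure is a case.
#' @param age_group_weights Named mixture over infant, child, adolescent,
#'   adult, elderly, unknown; ages are drawn uniformly within the bin
#'   (elderly up to 100; unknown gives a missing age).
#' @param sex_probs Named probabilities over male, female, not_reported.
#' @param profession_probs,setting_probs Reporter mixtures (drawn
#'   independently of each other).
#' @param reactions_per_case Probabilities of 1, 2 or 3 violence reactions
#'   on a case report.
#' @param violence_pt_weights Named weights (PT names from the narrow SMQ
#'   set) for the violence PT draw.
#' @param non_violence_pts PT names used for the single reaction of
#'   non-case reports.
#' @param seriousness_probs Named per-reaction probabilities over `none`
#'   and the six seriousness criteria.
#' @param outcome_probs Named per-reaction outcome probabilities; the fatal
#'   outcome is tied to the fatal seriousness criterion, so these exclude
#'   `fatal` and are renormalized over non-fatal reactions.
#' @param causality_probs Named list of probability vectors, one per
#'   causality dimension.
#' @param year_range Two integers, inclusive receipt-year range.
#' @param seed Integer seed; part of the configuration so a config fully
#'   determines its database.
#' @return A validated `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             drug_catalogue,
                             background_violence_prob,
                             age_group_weights,
                             sex_probs,
                             profession_probs,
                             setting_probs,
                             reactions_per_case = c(`1` = 0.97, `2` = 0.02, `3` = 0.01),
                             violence_pt_weights,
                             non_violence_pts,
                             seriousness_probs,
                             outcome_probs,
                             causality_probs,
                             year_range = c(1984L, 2021L),
                             seed = 1L) {
  cfg <- structure(
    list(
      n_reports = as.integer(n_reports),
      drug_catalogue = tibble::as_tibble(drug_catalogue),
      background_violence_prob = background_violence_prob,
      age_group_weights = age_group_weights,
      sex_probs = sex_probs,
      profession_probs = profession_probs,
      setting_probs = setting_probs,
      reactions_per_case = reactions_per_case,
      violence_pt_weights = violence_pt_weights,
      non_violence_pts = non_violence_pts,
      seriousness_probs = seriousness_probs,
      outcome_probs = outcome_probs,
      causality_probs = causality_probs,
      year_range = as.integer(year_range),
      seed = as.integer(seed),
      version = GENERATOR_VERSION
    ),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Validate a synthetic generator configuration
#' @param cfg A `synthetic_config`.
#' @return `cfg` invisibly; aborts with a config error when invalid.
#' @export
validate_synthetic_config <- function(cfg) {
  check_probs <- function(p, what, sums_to_one = TRUE) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      abort(sprintf("%s must be probabilities in [0, 1]", what),
            class = "vigicase_config_error")
    }
    if (sums_to_one && abs(sum(p) - 1) > 1e-6) {
      abort(sprintf("%s must sum to 1 (got %.6f)", what, sum(p)),
            class = "vigicase_config_error")
    }
  }
  if (cfg$n_reports < 1) {
    abort("n_reports must be >= 1", class = "vigicase_config_error")
  }
  cat_cols <- c("drug_name", "atc_code", "baseline_exposure_prob",
                "violence_log_ror")
  if (!all(cat_cols %in% names(cfg$drug_catalogue))) {
    abort("drug_catalogue must have drug_name, atc_code, baseline_exposure_prob, violence_log_ror",
          class = "vigicase_config_error")
  }
  check_probs(cfg$drug_catalogue$baseline_exposure_prob,
              "baseline_exposure_prob", sums_to_one = FALSE)
  if (all(cfg$drug_catalogue$baseline_exposure_prob == 0)) {
    abort("infeasible config: all exposure probabilities are 0",
          class = "vigicase_config_error")
  }
  check_probs(cfg$background_violence_prob, "background_violence_prob",
              sums_to_one = FALSE)
  check_probs(cfg$age_group_weights, "age_group_weights")
  if (!setequal(names(cfg$age_group_weights), AGE_GROUPS)) {
    abort("age_group_weights must be named by the six age groups",
          class = "vigicase_config_error")
  }
  check_probs(cfg$sex_probs, "sex_probs")
  check_probs(cfg$profession_probs, "profession_probs")
  check_probs(cfg$setting_probs, "setting_probs")
  check_probs(cfg$reactions_per_case, "reactions_per_case")
  check_probs(cfg$violence_pt_weights, "violence_pt_weights")
  check_probs(cfg$seriousness_probs, "seriousness_probs")
  if (!setequal(names(cfg$seriousness_probs), c("none", SERIOUSNESS_CRITERIA))) {
    abort("seriousness_probs must cover 'none' and the six criteria",
          class = "vigicase_config_error")
  }
  check_probs(cfg$outcome_probs, "outcome_probs")
  for (dim in names(CAUSALITY_LEVELS)) {
    check_probs(cfg$causality_probs[[dim]], paste0("causality_probs$", dim))
  }
  invisible(cfg)
}

AGE_BIN_BOUNDS <- list(
  infant = c(0, 2), child = c(2, 12), adolescent = c(12, 18),
  adult = c(18, 65), elderly = c(65, 100)
)

#' Generate a synthetic spontaneous-report database
#'
#' Draws `cfg$n_reports` reports under the configured exposure, caseness,
#' demographic and reaction models (see the package vignette for the
#' generative model). Deterministic given the config (which includes the
#' seed).
#'
#' @param cfg A [synthetic_config()].
#' @param dictionary Terminology used to resolve the configured PT names to
#'   codes; defaults to the bundled mock dictionary.
#' @return List with `db` (a validated [report_db()]) and `manifest` (seed,
#'   config hash, generator version, and realized marginals: case count,
#'   per-drug case/exposure tallies, demographic tallies).
#' @export
generate_reports <- function(cfg, dictionary = load_dictionary()) {
  validate_synthetic_config(cfg)
  n <- cfg$n_reports
  cat <- cfg$drug_catalogue
  n_drugs <- nrow(cat)
  set.seed(cfg$seed)

  # 1. exposures, with whole-row redraw so every report has >= 1 drug
  draw_rows <- function(m) {
    vapply(cat$baseline_exposure_prob,
           function(p) as.logical(rbinom(m, 1L, p)),
           logical(m))
  }
  exposure <- matrix(draw_rows(n), nrow = n)
  empty <- which(rowSums(exposure) == 0)
  while (length(empty) > 0) {
    redraw <- matrix(draw_rows(length(empty)), nrow = length(empty))
    exposure[empty, ] <- redraw
    empty <- empty[rowSums(redraw) == 0]
  }

  # 2. caseness under the logistic exposure model
  eta <- qlogis(cfg$background_violence_prob) +
    as.vector(exposure %*% cat$violence_log_ror)
  is_case <- rbinom(n, 1L, plogis(eta)) == 1L

  # 3. demographics
  age_group <- sample(names(cfg$age_group_weights), n, replace = TRUE,
                      prob = cfg$age_group_weights)
  age <- rep(NA_real_, n)
  for (g in names(AGE_BIN_BOUNDS)) {
    i <- which(age_group == g)
    if (length(i) > 0) {
      b <- AGE_BIN_BOUNDS[[g]]
      age[i] <- round(runif(length(i), b[1], b[2]), 1)
    }
  }
  age[!is.na(age) & age > 120] <- 120
  sex <- sample(names(cfg$sex_probs), n, replace = TRUE, prob = cfg$sex_probs)

  # 4.-5. reporter and receipt date
  profession <- sample(names(cfg$profession_probs), n, replace = TRUE,
                       prob = cfg$profession_probs)
  setting <- sample(names(cfg$setting_probs), n, replace = TRUE,
                    prob = cfg$setting_probs)
  year <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n, replace = TRUE)
  yday <- sample.int(365L, n, replace = TRUE)
  received <- as.Date(sprintf("%d-01-01", year)) + (yday - 1L)

  report_id <- sprintf("S%d-%07d", cfg$seed, seq_len(n))

  # 6. reactions
  violence_codes <- pt_code_for_name(dictionary, names(cfg$violence_pt_weights))
  if (anyNA(violence_codes)) {
    abort("violence_pt_weights name PTs absent from the dictionary",
          class = "vigicase_config_error")
  }
  nonviol_codes <- pt_code_for_name(dictionary, cfg$non_violence_pts)
  if (anyNA(nonviol_codes)) {
    abort("non_violence_pts name PTs absent from the dictionary",
          class = "vigicase_config_error")
  }
  case_idx <- which(is_case)
  k <- if (length(case_idx) > 0) {
    sample(as.integer(names(cfg$reactions_per_case)), length(case_idx),
           replace = TRUE, prob = cfg$reactions_per_case)
  } else {
    integer(0)
  }
  # PTs are distinct within a report, so a small term set caps the count
  k <- pmin(k, length(violence_codes))
  w <- cfg$violence_pt_weights / sum(cfg$violence_pt_weights)
  case_pts <- unlist(lapply(k, function(ki) {
    sample(violence_codes, ki, prob = w)
  }))
  noncase_idx <- which(!is_case)
  noncase_pts <- sample(nonviol_codes, length(noncase_idx), replace = TRUE)
  rxn_report_id <- c(rep(report_id[case_idx], times = k),
                     report_id[noncase_idx])
  rxn_pt <- c(case_pts, noncase_pts)
  n_rxn <- length(rxn_pt)

  # 7. seriousness and outcome
  crit <- sample(names(cfg$seriousness_probs), n_rxn, replace = TRUE,
                 prob = cfg$seriousness_probs)
  out_levels <- setdiff(names(cfg$outcome_probs), "fatal")
  out_probs <- cfg$outcome_probs[out_levels] / sum(cfg$outcome_probs[out_levels])
  outcome <- sample(out_levels, n_rxn, replace = TRUE, prob = out_probs)
  outcome[crit == "fatal"] <- "fatal"

  reactions <- tibble::tibble(
    report_id = rxn_report_id,
    pt_code = rxn_pt,
    seriousness_criteria = lapply(crit, function(cr) {
      if (cr == "none") character(0) else cr
    }),
    outcome = outcome
  )
  serious_by_report <- tapply(crit != "none", rxn_report_id, any)
  serious <- as.logical(serious_by_report[report_id])

  # 8. causality (cases only)
  causality <- if (length(case_idx) > 0) {
    draws <- lapply(names(CAUSALITY_LEVELS), function(dim) {
      p <- cfg$causality_probs[[dim]]
      sample(names(p), length(case_idx), replace = TRUE, prob = p)
    })
    names(draws) <- names(CAUSALITY_LEVELS)
    tibble::tibble(report_id = report_id[case_idx], !!!draws)
  } else {
    NULL
  }

  # 9. drug entries with roles
  exp_idx <- which(exposure, arr.ind = TRUE)
  exp_idx <- exp_idx[order(exp_idx[, 1], exp_idx[, 2]), , drop = FALSE]
  role <- sample(DRUG_ROLES, nrow(exp_idx), replace = TRUE,
                 prob = c(0.85, 0.08, 0.07))
  drugs <- tibble::tibble(
    report_id = report_id[exp_idx[, 1]],
    drug_name = cat$drug_name[exp_idx[, 2]],
    atc_code = cat$atc_code[exp_idx[, 2]],
    role = role
  )

  reports <- tibble::tibble(
    report_id = report_id,
    received_date = received,
    reporter_profession = profession,
    reporter_setting = setting,
    patient_age = age,
    patient_sex = sex,
    serious = serious
  )
  db <- report_db(reports, drugs, reactions, causality)

  case_ids <- report_id[case_idx]
  drug_tallies <- drugs |>
    dplyr::distinct(.data$report_id, .data$drug_name) |>
    dplyr::mutate(case = .data$report_id %in% case_ids) |>
    dplyr::group_by(.data$drug_name) |>
    dplyr::summarise(a = sum(.data$case), exposed = dplyr::n(),
                     .groups = "drop")
  manifest <- list(
    seed = cfg$seed,
    version = cfg$version,
    config_hash = rlang::hash(cfg),
    n_reports = n,
    case_count = length(case_idx),
    drug_tallies = drug_tallies,
    age_group_counts = as.list(table(age_group)),
    sex_counts = as.list(table(sex))
  )
  list(db = db, manifest = manifest)
}

#' Analytic expected case count under a configuration
#'
#' Uses the rare-event approximation: for a report the case probability is
#' approximately p0 times the product of exp(beta) over exposed drugs, and
#' exposure rows are conditioned on containing at least one drug. The
#' expectation is n p0 (M - P0) / (1 - P0) with
#' M = prod(1 - e + e exp(beta)) and P0 = prod(1 - e) over the catalogue.
#'
#' @param cfg A [synthetic_config()].
#' @return Expected number of case reports (numeric).
#' @export
expected_case_count <- function(cfg) {
  e <- cfg$drug_catalogue$baseline_exposure_prob
  or <- exp(cfg$drug_catalogue$violence_log_ror)
  m <- prod(1 - e + e * or)
  p0_empty <- prod(1 - e)
  cfg$n_reports * cfg$background_violence_prob *
    (m - p0_empty) / (1 - p0_empty)
}

solve_background_rate <- function(target_fraction, drug_catalogue) {
  e <- drug_catalogue$baseline_exposure_prob
  or <- exp(drug_catalogue$violence_log_ror)
  m <- prod(1 - e + e * or)
  p0_empty <- prod(1 - e)
  target_fraction * (1 - p0_empty) / (m - p0_empty)
}

# Effect drugs: the 16 substances most often suspected in violence cases,
# with effect sizes at their screened reporting odds ratios. Exposure
# baselines are back-derived with complete_table() from the case count,
# the ROR, 533 cases and 353,165 reports -- plausible magnitudes, not
# published exposure data. Lorazepam showed no disproportionality; it gets
# a modest non-null effect below every screening threshold.
preset_effect_drugs <- function() {
  spec <- tibble::tribble(
    ~drug_name, ~atc_code, ~a, ~ror,
    "montelukast", "R03DC03", 35, 17.85,
    "levetiracetam", "N03AX14", 23, 12.65,
    "bupropion", "N07BA02", 18, 11.19,
    "donepezil", "N06DA02", 14, 19.47,
    "perampanel", "N03AX22", 13, 59.14,
    "quetiapine", "N05AH04", 13, 6.18,
    "fluoxetine", "N06AB03", 13, 3.79,
    "lorazepam", "N05BA06", 12, 1.50,
    "zolpidem", "N05CF02", 11, 4.82,
    "escitalopram", "N06AB10", 11, 3.42,
    "methylphenidate", "N06BA04", 11, 13.97,
    "memantine", "N06DX01", 10, 22.09,
    "varenicline", "N07BA03", 10, 8.79,
    "olanzapine", "N05AH03", 9, 5.18,
    "azithromycin", "J01FA10", 8, 2.72,
    "duloxetine", "N06AX21", 8, 3.16
  )
  exposed_frac <- vapply(seq_len(nrow(spec)), function(i) {
    tab <- complete_table(spec$a[i], 533, 353165, spec$ror[i])
    (tab$a + tab$b) / 353165
  }, numeric(1))
  tibble::tibble(
    drug_name = spec$drug_name,
    atc_code = spec$atc_code,
    baseline_exposure_prob = exposed_frac,
    violence_log_ror = log(spec$ror)
  )
}

# Null background catalogue of commonly reported drugs; exposure
# probabilities chosen so reports average roughly two drug mentions and
# few exposure rows need redrawing.
preset_background_drugs <- function() {
  tibble::tribble(
    ~drug_name, ~atc_code, ~baseline_exposure_prob,
    "paracetamol", "N02BE01", 0.35,
    "omeprazole", "A02BC01", 0.28,
    "ibuprofen", "M01AE01", 0.25,
    "amoxicillin", "J01CA04", 0.16,
    "metformin", "A10BA02", 0.13,
    "acetylsalicylic acid", "B01AC06", 0.13,
    "simvastatin", "C10AA01", 0.11,
    "atorvastatin", "C10AA05", 0.11,
    "enalapril", "C09AA02", 0.09,
    "diclofenac", "M01AB05", 0.09,
    "amlodipine", "C08CA01", 0.09,
    "salbutamol", "R03AC02", 0.07,
    "levothyroxine", "H03AA01", 0.07,
    "furosemide", "C03CA01", 0.07,
    "tramadol", "N02AX02", 0.06,
    "ciprofloxacin", "J01MA02", 0.05,
    "ranitidine", "A02BA02", 0.05,
    "prednisone", "H02AB07", 0.04,
    "cetirizine", "R06AE07", 0.04,
    "warfarin", "B01AA03", 0.03
  ) |>
    dplyr::mutate(violence_log_ror = 0)
}

#' Preset emulating a national pharmacovigilance database
#'
#' A configuration whose marginal structure mirrors the study database:
#' 353,165 reports with a violence case fraction of 0.15%, a drug catalogue
#' holding the 16 most-reported suspected substances at their screened
#' effect sizes plus 20 null background drugs, demographics and reaction
#' profiles matching the reported case series (age groups, sex, reporter
#' mix, outcome and seriousness distributions, causality profile). The
#' background case rate is solved so the expected case fraction equals the
#' target exactly under the rare-event expectation.
#'
#' @param n_reports Database size; the full scale is 353,165, and smaller
#'   values (e.g. 50,000) give proportionally scaled databases for fast
#'   replication studies.
#' @param case_fraction Target marginal case fraction (default 533/353165).
#' @param null_effects Set every `violence_log_ror` to 0 (a null database
#'   for calibration checks) while keeping all marginals otherwise equal.
#' @param seed Integer seed stored in the config.
#' @return A [synthetic_config()].
#' @export
fedra_like_preset <- function(n_reports = 353165, case_fraction = 533 / 353165,
                              null_effects = FALSE, seed = 1L) {
  catalogue <- dplyr::bind_rows(preset_effect_drugs(), preset_background_drugs())
  if (null_effects) {
    catalogue$violence_log_ror <- 0
  }
  p0 <- solve_background_rate(case_fraction, catalogue)
  synthetic_config(
    n_reports = n_reports,
    drug_catalogue = catalogue,
    background_violence_prob = p0,
    age_group_weights = c(infant = 5, child = 80, adolescent = 42,
                          adult = 232, elderly = 169, unknown = 5) / 533,
    sex_probs = c(male = 315, female = 208, not_reported = 10) / 533,
    profession_probs = c(physician = 361, pharmacist = 116, nurse = 20,
                         other_health_professional = 20, consumer = 10,
                         not_reported = 6) / 533,
    setting_probs = c(out_of_hospital = 332, in_hospital = 145,
                      not_reported = 56) / 533,
    reactions_per_case = c(`1` = 0.97, `2` = 0.02, `3` = 0.01),
    violence_pt_weights = c(
      "aggression" = 480, "behavioural disturbance" = 35,
      "anger reaction" = 19, "hostility" = 10,
      "symptom related to violence" = 4, "homicidal ideation" = 3,
      "antisocial behaviour" = 2, "intermittent explosive disorder" = 1
    ) / 554,
    non_violence_pts = c("nausea", "vomiting", "diarrhoea", "headache",
                         "dizziness", "somnolence", "rash", "pruritus",
                         "pyrexia", "fatigue", "insomnia", "hepatotoxicity",
                         "anaemia"),
    seriousness_probs = c(none = 237, fatal = 3, life_threatening = 35,
                          hospital_admission = 65,
                          prolonged_hospitalisation = 5, disability = 2,
                          medically_significant = 207) / 554,
    outcome_probs = c(recovered = 353, recovering = 39, not_recovered = 47,
                      recovered_with_sequelae = 7, fatal = 3,
                      not_reported = 105) / 554,
    causality_probs = list(
      time_sequence = c(compatible = 0.966, incompatible = 0.004,
                        unknown = 0.030),
      prior_knowledge = c(well_known = 0.756, known = 0.150,
                          unknown = 0.094),
      dechallenge = c(withdrawal_with_improvement = 0.680,
                      withdrawal_without_improvement = 0.050,
                      no_withdrawal = 0.100, fatal_or_irreversible = 0.007,
                      unknown = 0.163),
      rechallenge = c(positive = 0.020, negative = 0.016,
                      none_or_unknown = 0.964),
      alternative_cause = c(no_information = 0.320 / 0.956,
                            ruled_out = 0.444 / 0.956,
                            equally_or_less_plausible_alternative = 0.192 / 0.956)
    ),
    year_range = c(1984L, 2021L),
    seed = seed
  )
}
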