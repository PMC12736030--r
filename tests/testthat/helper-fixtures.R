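# Fixture builders shared across the suite. All fixtures are constructed in
# code; randomized ones take an explicit seed.

the_dict <- load_dictionary()

pt <- function(name) pt_code_for_name(the_dict, name)

# A minimal hand-built database: n_total reports, the first `case_pts` get
# one violence reaction each, the rest a background reaction. `exposed`
# gives the indices of reports carrying `drug` as suspect.
tiny_db <- function(n_total = 10,
                    case_pts = rep("aggression", 3),
                    exposed = integer(0),
                    drug = c("montelukast", "R03DC03")) {
  ids <- sprintf("R%03d", seq_len(n_total))
  n_case <- length(case_pts)
  reports <- tibble::tibble(
    report_id = ids,
    received_date = as.Date("2014-06-01"),
    reporter_profession = "physician",
    reporter_setting = "out_of_hospital",
    patient_age = 40,
    patient_sex = "male",
    serious = FALSE
  )
  drugs <- tibble::tibble(
    report_id = ids, drug_name = "paracetamol",
    atc_code = "N02BE01", role = "suspect"
  )
  if (length(exposed) > 0) {
    drugs <- dplyr::bind_rows(drugs, tibble::tibble(
      report_id = ids[exposed], drug_name = drug[1],
      atc_code = drug[2], role = "suspect"
    ))
  }
  reactions <- tibble::tibble(
    report_id = ids,
    pt_code = c(pt(case_pts), rep(pt("nausea"), n_total - n_case)),
    seriousness_criteria = rep(list(character(0)), n_total),
    outcome = "recovered"
  )
  report_db(reports, drugs, reactions)
}

# Random valid database for property tests: 1-3 drugs and 1-2 reactions per
# report, violence PTs mixed in at `violence_prob`.
random_db <- function(n, seed, violence_prob = 0.3) {
  set.seed(seed)
  ids <- sprintf("X%05d", seq_len(n))
  catalogue <- data.frame(
    drug_name = c("montelukast", "levetiracetam", "paracetamol",
                  "omeprazole", "ibuprofen"),
    atc_code = c("R03DC03", "N03AX14", "N02BE01", "A02BC01", "M01AE01")
  )
  viol <- smq_terms(the_dict, "hostility_aggression", "broad")
  nonviol <- setdiff(the_dict$pt_records$pt_code, viol)
  reports <- tibble::tibble(
    report_id = ids,
    received_date = as.Date("1984-01-01") +
      sample.int(13000, n, replace = TRUE),
    reporter_profession = sample(c("physician", "pharmacist", "nurse",
                                   "not_reported"), n, replace = TRUE),
    reporter_setting = sample(c("in_hospital", "out_of_hospital",
                                "not_reported"), n, replace = TRUE),
    patient_age = ifelse(runif(n) < 0.1, NA_real_,
                         round(runif(n, 0, 99), 1)),
    patient_sex = sample(c("male", "female", "not_reported"), n,
                         replace = TRUE, prob = c(0.55, 0.4, 0.05)),
    serious = FALSE
  )
  drugs <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    j <- sample(nrow(catalogue), k)
    data.frame(report_id = ids[i], drug_name = catalogue$drug_name[j],
               atc_code = catalogue$atc_code[j],
               role = sample(c("suspect", "concomitant", "interaction"),
                             k, replace = TRUE, prob = c(0.7, 0.2, 0.1)))
  }))
  reactions <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:2, 1, prob = c(0.8, 0.2))
    codes <- vapply(seq_len(k), function(j) {
      if (runif(1) < violence_prob) sample(viol, 1) else sample(nonviol, 1)
    }, character(1))
    data.frame(report_id = ids[i], pt_code = codes)
  }))
  crit <- lapply(seq_len(nrow(reactions)), function(i) {
    if (runif(1) < 0.4) {
      sample(c("life_threatening", "hospital_admission",
               "medically_significant"), sample(1:2, 1))
    } else {
      character(0)
    }
  })
  reactions <- tibble::tibble(
    report_id = reactions$report_id,
    pt_code = reactions$pt_code,
    seriousness_criteria = crit,
    outcome = sample(setdiff(REACTION_OUTCOMES_TEST, "fatal"),
                     nrow(reactions), replace = TRUE)
  )
  has_crit <- vapply(crit, length, integer(1)) > 0
  serious <- as.logical(tapply(has_crit, reactions$report_id, any)[ids])
  reports$serious <- serious
  causality <- tibble::tibble(
    report_id = sample(ids, max(1, n %/% 3)),
    time_sequence = "compatible",
    prior_knowledge = "well_known",
    dechallenge = "withdrawal_with_improvement",
    rechallenge = "none_or_unknown",
    alternative_cause = "ruled_out"
  )
  report_db(reports, tibble::as_tibble(drugs), reactions, causality)
}

REACTION_OUTCOMES_TEST <- c("recovered", "recovering", "not_recovered",
                            "recovered_with_sequelae", "fatal", "not_reported")

# Independent brute-force case selection: scan every (report, reaction) pair.
brute_force_case_ids <- function(db, dictionary, smq_name, scope) {
  terms <- smq_terms(dictionary, smq_name, scope)
  out <- character(0)
  for (id in db$reports$report_id) {
    pts <- db$reactions$pt_code[db$reactions$report_id == id]
    if (any(pts %in% terms)) out <- c(out, id)
  }
  out
}

# Independent brute-force 2x2 construction: double loop over reports.
brute_force_table <- function(db, dictionary, smq_name, scope, drug_name,
                              roles = c("suspect", "interaction")) {
  case_ids <- brute_force_case_ids(db, dictionary, smq_name, scope)
  a <- b <- c_ <- d <- 0
  for (id in db$reports$report_id) {
    rows <- db$drugs[db$drugs$report_id == id, ]
    exposed <- any(rows$drug_name == drug_name & rows$role %in% roles)
    case <- id %in% case_ids
    if (case && exposed) a <- a + 1
    else if (!case && exposed) b <- b + 1
    else if (case && !exposed) c_ <- c_ + 1
    else d <- d + 1
  }
  c(a = a, b = b, c = c_, d = d)
}

random_2x2 <- function(seed, n_tables, min_cell = 1, max_cell = 200) {
  set.seed(seed)
  matrix(sample(min_cell:max_cell, 4 * n_tables, replace = TRUE), ncol = 4)
}
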