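# A case database whose reaction-level marginals equal the study's case
# series: 533 reports carrying 554 violence reactions with the published
# PT and outcome distributions.
case_series_db <- function() {
  pt_counts <- c(
    "aggression" = 480, "behavioural disturbance" = 35,
    "anger reaction" = 19, "hostility" = 10,
    "symptom related to violence" = 4, "homicidal ideation" = 3,
    "antisocial behaviour" = 2, "intermittent explosive disorder" = 1
  )
  outcome_counts <- c(
    not_reported = 105, recovering = 39, fatal = 3, not_recovered = 47,
    recovered = 353, recovered_with_sequelae = 7
  )
  n_rxn <- sum(pt_counts) # 554
  n_rep <- 533
  ids <- sprintf("C%03d", seq_len(n_rep))
  rxn_report <- c(ids, ids[seq_len(n_rxn - n_rep)])
  pts <- pt(rep(names(pt_counts), pt_counts))
  outcome <- rep(names(outcome_counts), outcome_counts)
  crit <- lapply(outcome, function(o) {
    if (o == "fatal") "fatal" else character(0)
  })
  serious <- as.logical(
    tapply(vapply(crit, length, integer(1)) > 0, rxn_report, any)[ids])
  reports <- tibble::tibble(
    report_id = ids,
    received_date = as.Date("2014-06-01"),
    reporter_profession = "physician",
    reporter_setting = "out_of_hospital",
    patient_age = 40, patient_sex = "male",
    serious = serious
  )
  drugs <- tibble::tibble(report_id = ids, drug_name = "montelukast",
                          atc_code = "R03DC03", role = "suspect")
  reactions <- tibble::tibble(report_id = rxn_report, pt_code = pts,
                              seriousness_criteria = crit, outcome = outcome)
  report_db(reports, drugs, reactions)
}

test_that("age groups bin deterministically with lower-inclusive edges", {
  expect_identical(
    as.character(assign_age_group(c(1.5, 2, 11.9, 12, 17.9, 18, 65, 65.1, NA))),
    c("infant", "child", "child", "adolescent", "adolescent", "adult",
      "adult", "elderly", "unknown"))
  expect_error(assign_age_group(-1), "non-negative")
  # total over [0, inf) plus absent
  set.seed(42)
  ages <- c(runif(500, 0, 119), NA)
  expect_false(anyNA(assign_age_group(ages)))
})

test_that("PT tabulation reproduces the published reaction-level percentages", {
  db <- case_series_db()
  tab <- tabulate_reactions_by_pt(db, the_dict)
  expect_identical(attr(tab, "denominator_kind"), "reactions")
  expect_equal(attr(tab, "denominator"), 554)
  expect_equal(tab$percentage[tab$key == "aggression"], 86.6)
  expect_equal(tab$percentage[tab$key == "behavioural disturbance"], 6.3)
  expect_equal(sum(tab$count), 554)
  # single-reaction degenerate case
  one <- tabulate_reactions_by_pt(tiny_db(1, case_pts = "hostility"), the_dict)
  expect_equal(one$percentage, 100.0)
})

test_that("outcome tabulation reproduces the published outcome percentages", {
  db <- case_series_db()
  tab <- tabulate_outcomes(db, the_dict)
  expect_equal(sum(tab$count), 554)
  expect_equal(tab$percentage[tab$key == "recovered"], 63.7)
  expect_equal(tab$percentage[tab$key == "not_recovered"], 8.5)
  expect_equal(tab$percentage[tab$key == "fatal"], 0.5)
  all_rec <- tabulate_outcomes(tiny_db(2, case_pts = c("aggression", "aggression")),
                               the_dict)
  expect_equal(all_rec$percentage[all_rec$key == "recovered"], 100.0)
})

test_that("half-up rounding reproduces every printed percentage from its count", {
  printed <- list(
    # PT table, denominator 554
    c(480, 86.6), c(35, 6.3), c(19, 3.4), c(10, 1.8), c(4, 0.7),
    c(3, 0.5), c(2, 0.4), c(1, 0.2),
    # outcome table, denominator 554
    c(105, 19.0), c(39, 7.0), c(3, 0.5), c(47, 8.5), c(353, 63.7), c(7, 1.3)
  )
  for (p in printed) {
    expect_equal(round_half_up(100 * p[1] / 554, 1), p[2])
  }
})

test_that("drug tabulation counts suspected entries with deterministic ties", {
  # 671 suspected entries, montelukast holding 35
  n <- 671
  ids <- sprintf("R%03d", seq_len(533))
  drug_names <- c(rep("montelukast", 35), rep("levetiracetam", 23),
                  rep("zzz_filler", n - 35 - 23))
  atc <- c(rep("R03DC03", 35), rep("N03AX14", 23), rep("N02BE01", n - 58))
  drugs <- tibble::tibble(
    report_id = rep(ids, length.out = n),
    drug_name = drug_names, atc_code = atc,
    role = c(rep("interaction", 5), rep("suspect", n - 5))
  )
  db <- tiny_db(533, case_pts = rep("aggression", 533))
  db$drugs <- drugs
  tab <- tabulate_drugs(db, level = "substance")
  expect_equal(attr(tab, "denominator"), 671)
  expect_equal(tab$percentage[tab$key == "montelukast"], 5.2)
  # level-1 partition conserves the denominator
  lvl1 <- tabulate_drugs(db, level = 1)
  expect_equal(sum(lvl1$count), 671)
  # excluding interactions shrinks the denominator by those 5 entries
  no_int <- tabulate_drugs(db, roles = "suspect")
  expect_equal(attr(no_int, "denominator"), 666)
  # alphabetical tie-break: equal counts sort by name
  tie <- freq_table(c(b_drug = 5, a_drug = 5), kind = "drug_entries")
  expect_identical(tie$key, c("a_drug", "b_drug"))
})

test_that("demographics use within-group denominators and conserve totals", {
  db <- tiny_db(80, case_pts = rep("aggression", 80))
  db$reports$patient_age <- round(runif(80, 2, 11.9), 1)
  db$reports$patient_sex <- c(rep("male", 53), rep("female", 26),
                              "not_reported")
  dem <- tabulate_demographics(db)
  child <- dplyr::filter(dem$sex_by_age_group, age_group == "child")
  expect_equal(child$percentage[child$sex == "male"], 66.3)
  expect_equal(child$percentage[child$sex == "female"], 32.5)
  expect_equal(sum(dem$age_group$count), n_reports(db))
  all_female <- tiny_db(5, case_pts = rep("hostility", 5))
  all_female$reports$patient_sex <- "female"
  dem2 <- tabulate_demographics(all_female)
  adult <- dplyr::filter(dem2$sex_by_age_group, age_group == "adult")
  expect_equal(adult$percentage[adult$sex == "female"], 100.0)
})

test_that("frequency tables conserve counts and write with their denominator", {
  for (seed in 1:3) {
    rdb <- random_db(25, seed = seed)
    sel <- select_cases(rdb, the_dict, "hostility_aggression", "broad")
    tab <- tabulate_reactions_by_pt(sel$cases, the_dict,
                                    scope = "broad")
    expect_true(all(tab$count >= 0 & tab$count == trunc(tab$count)))
    expect_equal(sum(tab$count), attr(tab, "denominator"))
    expect_lt(abs(sum(tab$percentage) - 100),
              0.05 * max(1, nrow(tab)))
  }
  tab <- freq_table(c(x = 2, y = 1), kind = "reports")
  f <- withr::local_tempfile(fileext = ".csv")
  write_freq_table(tab, f)
  lines <- readLines(f)
  expect_identical(lines[1], "# denominator=3 kind=reports")
  expect_identical(lines[2], "key,count,percentage")
})
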