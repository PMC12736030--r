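test_that("build_table counts reports once per cell and conserves the total", {
  db <- tiny_db(10, case_pts = rep("aggression", 3), exposed = c(1, 2, 4))
  tab <- build_table(db, the_dict, "hostility_aggression", "narrow",
                     "montelukast")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 1, 6))
  # unknown drug: empty exposure, not an error
  none <- build_table(db, the_dict, "hostility_aggression", "narrow",
                      "no_such_drug")
  expect_equal(c(none$a, none$b), c(0, 0))
  expect_equal(none$c + none$d, 10)
})

test_that("build_table equals a brute-force double loop on random reports", {
  db <- random_db(200, seed = 99)
  for (drug in c("montelukast", "levetiracetam", "paracetamol")) {
    tab <- build_table(db, the_dict, "hostility_aggression", "narrow", drug)
    bf <- brute_force_table(db, the_dict, "hostility_aggression", "narrow",
                            drug)
    expect_equal(c(tab$a, tab$b, tab$c, tab$d), unname(bf))
    expect_equal(tab$a + tab$b + tab$c + tab$d, 200)
  }
  # suspected-role definition: concomitant-only mentions are unexposed
  bf_strict <- brute_force_table(db, the_dict, "hostility_aggression",
                                 "narrow", "omeprazole", roles = "suspect")
  tab_strict <- build_table(db, the_dict, "hostility_aggression", "narrow",
                            "omeprazole", roles = "suspect")
  expect_equal(c(tab_strict$a, tab_strict$b), unname(bf_strict[c("a", "b")]))
})

test_that("ROR point estimate, CI and symmetries behave as the formula dictates", {
  unit <- compute_ror(contingency_table(1, 1, 1, 1))
  expect_equal(unit$estimate, 1.0)
  expect_equal(log(unit$ci[1]), -log(unit$ci[2])) # symmetric about 1 on log scale
  tabs <- random_2x2(seed = 5, n_tables = 50)
  for (i in seq_len(nrow(tabs))) {
    t1 <- contingency_table(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    r1 <- compute_ror(t1)
    expect_true(r1$ci[1] < r1$estimate && r1$estimate < r1$ci[2])
    # swapping rows with columns fixed maps ROR to its inverse
    t_swap <- contingency_table(tabs[i, 2], tabs[i, 1], tabs[i, 4], tabs[i, 3])
    expect_equal(compute_ror(t_swap)$estimate, 1 / r1$estimate)
    # transposing exposure and caseness labels leaves the ROR unchanged
    t_tr <- contingency_table(tabs[i, 1], tabs[i, 3], tabs[i, 2], tabs[i, 4])
    expect_equal(compute_ror(t_tr)$estimate, r1$estimate)
  }
})

test_that("zero cells give an explicitly undefined result or a flagged correction", {
  z <- contingency_table(0, 10, 5, 100)
  none <- compute_ror(z, signal_thresholds(zero_cell_correction = "none"))
  expect_true(is.na(none$estimate) && all(is.na(none$ci)))
  hald <- compute_ror(z) # haldane default
  expect_true(hald$corrected)
  expect_equal(hald$estimate, (0.5 * 100.5) / (10.5 * 5.5))
})

test_that("PRR equals 1 at equal proportions and never exceeds ROR above 1", {
  eq <- compute_prr(contingency_table(10, 90, 20, 180))
  expect_equal(eq$estimate, 1.0)
  tabs <- random_2x2(seed = 7, n_tables = 200)
  for (i in seq_len(nrow(tabs))) {
    tab <- contingency_table(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    ror <- compute_ror(tab)$estimate
    prr <- compute_prr(tab)$estimate
    if (ror > 1) expect_lte(prr, ror)
    if (abs(ror - 1) < 1e-12) expect_equal(prr, 1)
  }
})

test_that("Yates chi-square matches hand computation and an independent implementation", {
  # proportional table: ad = bc
  expect_equal(compute_chi2_yates(contingency_table(10, 20, 30, 60)), 0)
  # frozen hand computation of N(|ad-bc|-N/2)^2 / prod(margins)
  expect_equal(compute_chi2_yates(contingency_table(10, 10, 10, 70)),
               11.81640625, tolerance = 1e-10)
  # clamp: correction exceeding |ad-bc| must give exactly 0, not negative
  expect_equal(compute_chi2_yates(contingency_table(5, 5, 5, 6)), 0)
  tabs <- random_2x2(seed = 11, n_tables = 1000)
  for (i in seq_len(nrow(tabs))) {
    tab <- contingency_table(tabs[i, 1], tabs[i, 2], tabs[i, 3], tabs[i, 4])
    ours <- compute_chi2_yates(tab)
    ref <- suppressWarnings(stats::chisq.test(
      matrix(tabs[i, ], 2, byrow = TRUE), correct = TRUE))$statistic
    expect_equal(ours, unname(ref), tolerance = 1e-10)
  }
  expect_true(is.na(compute_chi2_yates(contingency_table(0, 0, 5, 5))))
})

test_that("signal evaluation applies all four strict thresholds", {
  # published headline drug: all criteria met
  s <- evaluate_signal(n = 35, ror_ci_low = 12.62, prr = 17.43,
                       chi2 = 478.66)
  expect_true(s$signal)
  expect_setequal(s$criteria_met, c("min_reports", "ror_ci_low_gt_1",
                                    "prr_gt_2", "chi2_gt_4"))
  # two reports with an enormous ROR still fail the minimum-report rule
  s2 <- evaluate_signal(n = 2, ror_ci_low = 50, prr = 100, chi2 = 300)
  expect_false(s2$signal)
  expect_false("min_reports" %in% s2$criteria_met)
  # boundaries are strict
  expect_false(evaluate_signal(5, ror_ci_low = 1.0, prr = 17, chi2 = 17)$signal)
  expect_false(evaluate_signal(5, ror_ci_low = 1.2, prr = 2.0, chi2 = 17)$signal)
  expect_false(evaluate_signal(5, ror_ci_low = 1.2, prr = 17, chi2 = 4.0)$signal)
})

test_that("screen flags exactly the constructed association", {
  # one strongly associated drug: 6 of 8 cases exposed, 4 of 192 non-cases;
  # background drug on every report stays unflagged
  n <- 200
  ids <- sprintf("R%03d", seq_len(n))
  case_idx <- 1:8
  reports <- tibble::tibble(
    report_id = ids, received_date = as.Date("2010-01-01"),
    reporter_profession = "physician", reporter_setting = "in_hospital",
    patient_age = 50, patient_sex = "female", serious = FALSE
  )
  drugs <- dplyr::bind_rows(
    tibble::tibble(report_id = ids, drug_name = "paracetamol",
                   atc_code = "N02BE01", role = "suspect"),
    tibble::tibble(report_id = ids[c(1:6, 101:104)],
                   drug_name = "perampanel", atc_code = "N03AX22",
                   role = "suspect")
  )
  reactions <- tibble::tibble(
    report_id = ids,
    pt_code = c(pt(rep("aggression", 8)), pt(rep("nausea", n - 8))),
    seriousness_criteria = rep(list(character(0)), n),
    outcome = "recovered"
  )
  db <- report_db(reports, drugs, reactions)
  res <- screen(db, the_dict, "hostility_aggression", "narrow")
  expect_true(all(res$n >= 3))
  expect_identical(res$drug_name[res$signal], "perampanel")
  expect_false(res$signal[res$drug_name == "paracetamol"])
  # empty case set: empty result, not an error
  db0 <- tiny_db(5, case_pts = character(0))
  expect_equal(nrow(screen(db0, the_dict, "hostility_aggression", "narrow")), 0)
})

test_that("screen margins agree with select_cases and per-drug tables", {
  db <- random_db(150, seed = 3)
  sel <- select_cases(db, the_dict, "hostility_aggression", "narrow")
  res <- screen(db, the_dict, "hostility_aggression", "narrow")
  for (i in seq_len(nrow(res))) {
    expect_equal(res$a[i] + res$c[i], length(sel$case_ids))
    expect_equal(res$a[i] + res$b[i] + res$c[i] + res$d[i], n_reports(db))
    tab <- build_table(db, the_dict, "hostility_aggression", "narrow",
                       res$drug_name[i])
    expect_equal(res$a[i], tab$a)
    expect_equal(res$b[i], tab$b)
  }
})

test_that("complete_table inverts compute_ror in closed form", {
  # integer forward-then-invert: table (2,1,1,6) has ROR 12
  fwd <- contingency_table(2, 1, 1, 6)
  ror <- compute_ror(fwd)$estimate
  expect_equal(ror, 12)
  back <- complete_table(2, 3, 10, ror)
  expect_equal(back$b, 1)
  expect_equal(back$d, 6)
  expect_true(back$derived)
  # independence limit: ror = 1 gives exposure independent of caseness
  ind <- complete_table(4, 20, 120, 1)
  expect_equal(ind$b, 4 * (120 - 20) / 20)
  # round-trip to at least 6 significant digits on random integer tables
  tabs <- random_2x2(seed = 13, n_tables = 100, min_cell = 1, max_cell = 500)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs[i, 1]; b <- tabs[i, 2]; c_ <- tabs[i, 3]; d <- tabs[i, 4]
    ror_i <- compute_ror(contingency_table(a, b, c_, d))$estimate
    comp <- complete_table(a, a + c_, a + b + c_ + d, ror_i)
    expect_equal(comp$b, b, tolerance = 1e-9)
    expect_equal(compute_ror(comp)$estimate, ror_i, tolerance = 1e-9)
  }
  expect_error(complete_table(5, 4, 10, 2), class = "vigicase_validation_error")
  expect_error(complete_table(2, 3, 10, -1), class = "vigicase_validation_error")
})

test_that("confidence intervals narrow as all cells scale up", {
  widths <- vapply(c(1, 10, 100), function(k) {
    ci <- compute_ror(contingency_table(5 * k, 20 * k, 50 * k, 400 * k))$ci
    log(ci[2]) - log(ci[1])
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
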