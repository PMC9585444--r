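test_that("build_contingency classifies the exhaustive tiny case", {
  rt <- as_report_table(tibble::tibble(
    report_id = 1:4,
    drugs = list("d", "d", character(), character()),
    events = list("e", character(), "e", character())))
  tab <- build_contingency(rt, "d", "e")
  expect_equal(unlist(tab[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))

  empty <- as_report_table(tibble::tibble(report_id = character(),
                                          drugs = list(), events = list()))
  tab0 <- build_contingency(empty, "d", "e")
  expect_equal(unlist(tab0[c("a", "b", "c", "d")]),
               c(a = 0, b = 0, c = 0, d = 0))
})

test_that("build_contingency equals a brute-force recount on random tables", {
  for (seed in 1:5) {
    cfg <- sim_config(seed = seed, n_drugs = 5, n_adrs = 4, n_reports = 300,
                      planted_pairs = data.frame(drug = "D0002",
                                                 adr = "A0003",
                                                 true_ror = 3),
                      baseline_drug_prob = 0.2, baseline_event_prob = 0.15)
    rt <- simulate_reports(cfg)$reports
    for (pair in list(c("D0002", "A0003"), c("D0001", "A0001"))) {
      tab <- build_contingency(rt, pair[1], pair[2])
      expect_equal(unlist(tab[c("a", "b", "c", "d")]),
                   contingency_oracle(rt, pair[1], pair[2]),
                   label = paste(seed, pair[1], pair[2]))
    }
  }
})

test_that("odds_ratio evaluates the closed forms", {
  ind <- odds_ratio(contingency_2x2(10, 10, 10, 10))
  expect_equal(ind$point, 1)
  expect_equal(ind$p_value, 1)

  est <- odds_ratio(contingency_2x2(20, 5, 10, 40))
  expect_equal(est$point, 16)
  expect_equal(est$log_se, sqrt(1 / 20 + 1 / 5 + 1 / 10 + 1 / 40))
  expect_equal(est$log_se, 0.612372, tolerance = 1e-6)
  expect_equal(est$ci_low, exp(log(16) - 1.959964 * est$log_se))
  expect_equal(est$ci_low, 4.82, tolerance = 0.005)
  expect_equal(est$ci_high, 53.1, tolerance = 0.005)
  expect_equal(est$n_units, 75)
})

test_that("zero cells error without correction and shift by 0.5 with it", {
  tab <- contingency_2x2(0, 10, 5, 40)
  expect_error(odds_ratio(tab, correction = FALSE), "degenerate")
  est <- odds_ratio(tab, correction = TRUE)
  expect_equal(est$point, (0.5 * 40.5) / (10.5 * 5.5))
  ## correction only applies when a cell is zero
  est2 <- odds_ratio(contingency_2x2(1, 10, 5, 40), correction = TRUE)
  expect_equal(est2$point, (1 * 40) / (10 * 5))
})

test_that("transposition and scale-equivariance properties hold", {
  set.seed(404)
  for (i in 1:50) {
    cells <- sample(1:200, 4, replace = TRUE)
    e1 <- odds_ratio(contingency_2x2(cells[1], cells[2], cells[3], cells[4]))
    e2 <- odds_ratio(contingency_2x2(cells[2], cells[1], cells[4], cells[3]))
    expect_equal(e1$point * e2$point, 1)
    k <- sample(2:9, 1)
    e3 <- odds_ratio(contingency_2x2(k * cells[1], k * cells[2],
                                     k * cells[3], k * cells[4]))
    expect_equal(e3$point, e1$point)
    expect_equal(e3$log_se, e1$log_se / sqrt(k))
  }
})

test_that("Wald and Pearson p-values broadly agree on clear signals", {
  tab <- contingency_2x2(40, 60, 20, 80)
  wald <- odds_ratio(tab)$p_value
  pear <- chisq_p(tab)
  expect_lt(wald, 0.01)
  expect_lt(pear, 0.01)
})

test_that("lab signal honors direction semantics and non-computability", {
  d <- demo_dictionary()
  hypo <- resolve_adr(d, "Hypokalemia")  # direction = low

  ## subject above range only -> contributes to the no-event margin
  exposures <- tibble::tibble(subject_id = c("S1", "S2"),
                              drug = "fluconazole", start_day = 0)
  labs <- tibble::tibble(
    subject_id = c("S1", "S2", "S3", "S4"),
    loinc_id = "2823_3", day = 5,
    value = c(2.8, 6.5, 2.9, 4.5),  # low, HIGH, low, normal
    ref_low = 3.5, ref_high = 5.5)
  sig <- ehr_lab_signal(exposures, labs, "fluconazole", hypo,
                        correction = TRUE)
  expect_equal(sig$table$a, 1)  # S1 low after exposure
  expect_equal(sig$table$b, 1)  # S2 high-only: not an event for "low"
  expect_equal(sig$table$c, 1)  # S3 unexposed, low
  expect_equal(sig$table$d, 1)

  ## abnormality before exposure does not count for the exposed
  labs_pre <- dplyr::mutate(labs, day = ifelse(subject_id == "S1", -2, 5))
  sig_pre <- ehr_lab_signal(exposures, labs_pre, "fluconazole", hypo,
                            correction = TRUE)
  expect_equal(sig_pre$table$a, 0)

  ## an ADR without any LOINC mapping is a value, not an exception
  bare <- pv_dictionary(
    drugs = data.frame(drug_id = "D1", name = "drugone",
                       atc_codes = "A01AA01"),
    adrs = data.frame(pt_name = "Rash", umls_cui = "C1", soc = "Skin"),
    quiet = TRUE)
  sig2 <- ehr_lab_signal(exposures, labs, "drugone",
                         resolve_adr(bare, "Rash"))
  expect_false(sig2$computable)
  expect_match(sig2$reason, "no laboratory mapping")

  ## nobody exposed -> degenerate table path, still a value
  sig3 <- ehr_lab_signal(exposures[0, ], labs, "fluconazole", hypo)
  expect_false(sig3$computable)
  expect_match(sig3$reason, "degenerate")
})

test_that("planted cohort OR is recovered with near-nominal CI coverage", {
  ## 200 seeded cohorts of 5,000 subjects with a planted OR of 2.0;
  ## the 95% CI should contain the planted value in >= 93% of runs
  d <- demo_dictionary()
  hypo <- resolve_adr(d, "Hypokalemia")
  hits <- vapply(1:200, function(s) {
    co <- simulate_cohort(n_subjects = 5000, true_or = 2, seed = s,
                          drug = "fluconazole")
    sig <- ehr_lab_signal(co$exposures, co$labs, "fluconazole", hypo,
                          correction = TRUE)
    sig$estimate$ci_low <= 2 && sig$estimate$ci_high >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("partner results ingest the printed-table dialect", {
  d <- demo_dictionary()
  est <- demo_partner_estimates(d)
  fam <- est[est$drug == "famotidine", ]
  expect_equal(nrow(fam), 4)
  expect_equal(fam$estimate_type, c("HR", "OR", "OR", "OR"))
  expect_equal(fam$point, c(1.79, 2.19, 1.11, 3.97))
  expect_equal(fam$p_is_bound, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(fam$pt_name, rep("Hepatic function abnormal", 4))
  ## bounded p "<.001" taken at .001: conservative (largest) SE
  expect_equal(fam$log_se[1], abs(log(1.79)) / qnorm(1 - 0.001 / 2))
  expect_equal(fam$se_source[1], "p-bound")
  expect_equal(fam$log_se[2], abs(log(2.19)) / qnorm(1 - 0.003 / 2))

  ## CI-based SE recovery: (1.60, 1.79) around 1.69
  one <- load_partner_results(tibble::tibble(
    partner_id = "M", drug = "d", adr = "a", estimate_type = "OR",
    point = 1.69, ci_low = 1.60, ci_high = 1.79, p_value = NA, n = NA))
  expect_equal(one$log_se, (log(1.79) - log(1.60)) / (2 * 1.959964))
  expect_equal(one$log_se, 0.028627, tolerance = 1e-4)
  expect_equal(one$se_source, "ci")

  expect_equal(nrow(load_partner_results(
    tibble::tibble(partner_id = character(), drug = character(),
                   adr = character(), estimate_type = character(),
                   point = character()))), 0)
  expect_error(load_partner_results(tibble::tibble(
    partner_id = "x", drug = "d", adr = "a", estimate_type = "OR",
    point = -1)), "non-positive")
  expect_error(load_partner_results(tibble::tibble(
    partner_id = "x", drug = "d", adr = "a", estimate_type = "OR",
    point = 2, p_value = "1.7")), "p_value")
})

test_that("signal_scan agrees with the single-pair route", {
  cfg <- sim_config(seed = 21, n_drugs = 6, n_adrs = 5, n_reports = 2000,
                    planted_pairs = data.frame(drug = "D0001", adr = "A0001",
                                               true_ror = 4))
  rt <- simulate_reports(cfg)$reports
  scan <- signal_scan(rt, min_a = 3)
  direct <- odds_ratio(build_contingency(rt, "D0001", "A0001"),
                       correction = TRUE)
  row <- scan[scan$drug == "D0001" & scan$adr == "A0001", ]
  expect_equal(row$point, direct$point)
  expect_equal(row$log_se, direct$log_se)
  expect_true(all(scan$n_units == nrow(rt)))
})
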