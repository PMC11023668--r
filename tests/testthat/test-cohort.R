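test_that("doses are parsed from free text and imputed by the drug-type median", {
  expect_equal(parse_dose("Simvastatin 40mg tablets"), 40)
  expect_equal(parse_dose("Atorvastatin 10 mg"), 10)
  expect_true(is.na(parse_dose("Metformin tablets")))
  expect_equal(parse_dose(c("A 2.5mg", "B 80MG caps")), c(2.5, 80))

  regs <- data.frame(drug_type = rep("simvastatin", 4),
                     start_dose = c(20, 40, 40, NA))
  expect_equal(impute_missing_dose(regs)$start_dose, c(20, 40, 40, 40))

  regs2 <- data.frame(drug_type = "simvastatin", start_dose = c(10, 80, NA))
  expect_equal(impute_missing_dose(regs2)$start_dose, c(10, 80, 45))

  regs3 <- data.frame(drug_type = "simvastatin", start_dose = c(20, 40))
  expect_equal(impute_missing_dose(regs3)$start_dose, c(20, 40))

  # a drug type with no observed dose is flagged, not imputed
  regs4 <- data.frame(drug_type = "rosuvastatin", start_dose = NA_real_)
  out <- impute_missing_dose(regs4)
  expect_true(out$dose_unavailable)
  expect_true(is.na(out$start_dose))
})

test_that("prescription classification resolves class, primary and combination flags", {
  map <- default_code_map()
  rx <- prescription_records(c("a", "a", "a"), c(0L, 10L, 20L),
                             c("SIMVA40", "SIMVEZE", "GLIC80"))
  ann <- classify_prescriptions(rx, map, primary = "statin")$records
  expect_identical(ann$broad_class, c("lipid", "lipid", "antidiabetic"))
  expect_identical(ann$is_primary, c(TRUE, FALSE, FALSE))
  expect_identical(ann$is_combination, c(FALSE, TRUE, FALSE))

  # sulfonylurea is same-class-other under a metformin analysis
  ann2 <- classify_prescriptions(rx, map, primary = "metformin")$records
  expect_true(ann2$is_same_class_other[3])
})

test_that("regularity enumerates two-month windows correctly", {
  # a prescription every 30 days covers every window
  expect_equal(regularity(seq(0, 600, by = 30), 0, 610), 1.0)
  # ten windows over [0, 610); days {0, 200, 400} cover three of them
  expect_equal(regularity(c(0, 200, 400), 0, 610), 0.3)
  expect_equal(regularity(numeric(0), 0, 610), 0)
  expect_error(regularity(c(0), 10, 10), "end")

  # property: adding a prescription never decreases regularity
  set.seed(42)
  for (i in 1:20) {
    d <- sort(sample(0:700, sample(1:10, 1)))
    extra <- sample(0:700, 1)
    expect_gte(regularity(c(d, extra), 0, 730), regularity(d, 0, 730))
  }
})

test_that("window measure selection follows the closest/earliest and average rules", {
  d <- c(-100, -30, 3); v <- c(5, 4, 3.5)
  # stringent baseline window [-90, +7], single: day +3 is closest to start
  sel <- select_window_measure(d, v, -90, 7, start = 0,
                               measure_mode = "single", pick = "closest")
  expect_equal(sel$value, 3.5)
  # average: mean of the two in-window measures
  sel <- select_window_measure(d, v, -90, 7, start = 0,
                               measure_mode = "average")
  expect_equal(sel$value, mean(c(4, 3.5)))
  expect_equal(sel$n, 2L)
  # only an out-of-window measure: missing
  expect_null(select_window_measure(-100, 5, -90, 7, 0, "single", "closest"))
  # tie at equal distance: the earlier (pre-treatment) measure wins
  sel <- select_window_measure(c(-5, 5), c(9, 1), -90, 7, 0, "single", "closest")
  expect_equal(sel$value, 9)
  # post window is half-open at the top
  expect_null(select_window_measure(730, 1, 183, 730, 0, "single", "earliest",
                                    inclusive_hi = FALSE))
})

test_that("co-medication rules distinguish violations from allowed add-ons", {
  map <- default_code_map()
  len <- scenario_config(mode = "lenient")
  str <- scenario_config(mode = "stringent")

  # statin start with an ezetimibe combination 100 days later: violation
  rx <- classify_prescriptions(
    prescription_records(c("a", "a"), c(0L, 100L), c("SIMVA40", "SIMVEZE")),
    map, "statin")$records
  reg <- build_regimen(rx, len, "statin")
  expect_identical(reg$comed_violation, "same_class_combination")

  # metformin with sulfonylurea at days -200/+300: add-on in lenient mode...
  rx2 <- classify_prescriptions(
    prescription_records(c("b", "b", "b"), c(0L, 100L, 300L),
                         c("METF500", "METF500", "METF500")),
    map, "metformin")$records
  su <- classify_prescriptions(
    prescription_records(c("b", "b"), c(0L, 0L), c("GLIC80", "GLIC80")),
    map, "metformin")$records
  su$date <- c(-200L, 300L)  # pre- and post-start sulfonylurea
  reg2 <- build_regimen(rbind(rx2, su), len, "metformin")
  expect_true(is.na(reg2$comed_violation))
  expect_identical(reg2$addon, "gliclazide")

  # ...but a violation under stringent filtering
  reg3 <- build_regimen(rbind(rx2, su), str, "metformin")
  expect_match(reg3$comed_violation, "same_class_comed")

  # switch detection: consecutive ingredient change
  rx4 <- classify_prescriptions(
    prescription_records(c("c", "c", "c"), c(0L, 61L, 122L),
                         c("SIMVA40", "SIMVA40", "ATORV40")),
    map, "statin")$records
  rx4$description <- c("Simvastatin 40mg", "Simvastatin 40mg",
                       "Atorvastatin 40mg")
  reg4 <- build_regimen(rx4, len, "statin")
  expect_identical(reg4$switch_kinds, "type_change")
  expect_identical(reg4$switch_dates, 122L)
})

test_that("the engineered six-person fixture removes one person per stage", {
  fx <- qc_fixture()
  out <- qc_cascade(fx$measures, fx$prescriptions, fx$map, fx$scenario,
                    primary = "statin", biomarker = "LDL")
  a <- out$audit
  expect_identical(a$input_n, 6L)
  expect_identical(a$survivors, 0L)
  stages6 <- c("comed", "baseline_post_measures", "prior_record",
               "rx_after_post", "drug_change", "regularity")
  expect_identical(a$removed[match(stages6, a$stages)], rep(1L, 6))
  expect_identical(sum(a$removed), 6L)
  # each person fails exactly at its engineered stage
  expect_identical(unname(a$first_fail[paste0("p", 1:6)]), stages6)
  # conservation
  expect_identical(a$input_n, a$survivors + sum(a$removed))
})

test_that("a low baseline is removed at the minimum-baseline stage only", {
  ok <- clean_person("ok1", baseline_value = 3.0)
  low <- clean_person("low1", baseline_value = 1.5)
  sc <- scenario_config(mode = "lenient", min_cohort_size = 1L,
                        min_drug_group_size = 1L)
  out <- qc_cascade(rbind(ok$measures, low$measures),
                    rbind(ok$prescriptions, low$prescriptions),
                    default_code_map(), sc)
  expect_identical(out$audit$survivors, 1L)
  expect_identical(unname(out$audit$first_fail[["low1"]]), "min_baseline")
  expect_identical(out$cohort$person_id, "ok1")
})

test_that("audit conservation and window correctness hold on random inputs", {
  for (seed in c(2, 5)) {
    b <- random_bundle(n = 250, seed = seed)
    sc <- scenario_config(mode = "lenient", min_cohort_size = 1L,
                          min_drug_group_size = 1L)
    out <- qc_cascade(b$measures, b$prescriptions, default_code_map(), sc,
                      persons = b$persons)
    a <- out$audit
    expect_identical(a$input_n, a$survivors + sum(a$removed))
    # every excluded person has exactly one first-failing stage
    expect_identical(sum(!is.na(a$first_fail)), sum(a$removed))
    if (nrow(out$cohort) > 0L) {
      co <- out$cohort
      expect_true(all(co$baseline_date >= co$start_date - sc$baseline_lookback_days))
      expect_true(all(co$baseline_date <= co$start_date + sc$baseline_after_days))
      expect_true(all(co$time_start_to_post >= sc$post_min_days))
      expect_true(all(co$time_start_to_post < sc$post_max_days))
      expect_true(all(co$regularity >= 0 & co$regularity <= 1))
    }
  }
})

test_that("stringent survivors are a subset of lenient survivors (single measures)", {
  b <- random_bundle(n = 400, seed = 8)
  common <- list(min_cohort_size = 1L, min_drug_group_size = 1L,
                 measure_mode = "single")
  len <- do.call(scenario_config, c(list(mode = "lenient"), common))
  str <- do.call(scenario_config, c(list(mode = "stringent"), common))
  s_len <- qc_cascade(b$measures, b$prescriptions, default_code_map(), len,
                      persons = b$persons)$cohort$person_id
  s_str <- qc_cascade(b$measures, b$prescriptions, default_code_map(), str,
                      persons = b$persons)$cohort$person_id
  expect_gt(length(s_len), 0L)
  expect_true(all(s_str %in% s_len))
})

test_that("the min_one regularity mode relaxes the threshold rule", {
  # one refill between start and post measure: fails the 0.8 threshold but
  # passes the single-prescription requirement
  ps <- person_stream("m1", c(1000, 1150, 1400), rep("SIMVA40", 3),
                      c(100, 950, 1300), c(3.2, 3.0, 2.5))
  base <- list(mode = "lenient", min_cohort_size = 1L,
               min_drug_group_size = 1L)
  thr <- do.call(scenario_config, c(base, regularity_mode = "threshold"))
  min1 <- do.call(scenario_config, c(base, regularity_mode = "min_one"))
  out_thr <- qc_cascade(ps$measures, ps$prescriptions, default_code_map(), thr)
  out_min <- qc_cascade(ps$measures, ps$prescriptions, default_code_map(), min1)
  expect_identical(unname(out_thr$audit$first_fail[["m1"]]), "regularity")
  expect_identical(out_min$audit$survivors, 1L)
})

test_that("control pairs keep the earliest qualifying spacing", {
  m <- measure_records(c("a", "a", "b", "b", "c", "c", "c"),
                       c(0, 400, 0, 100, 0, 100, 400),
                       "LDL", c(3, 2.9, 3, 3.1, 3, 3.2, 2.8), "mmol_per_L")
  cp <- control_pairs(m)
  expect_setequal(cp$person_id, c("a", "c"))   # b's measures are too close
  expect_equal(cp$spacing[cp$person_id == "a"], 400)
  # c: earliest qualifying pair is (0, 400), not (100, 400)
  expect_equal(cp$first_date[cp$person_id == "c"], 0)
  expect_equal(cp$second_date[cp$person_id == "c"], 400)
})
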