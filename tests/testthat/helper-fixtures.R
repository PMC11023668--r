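# Fixture builders shared across test files. Everything is generated in code.

# One person's records: prescriptions at rx_days (with codes) and LDL
# measures at meas_days (with values).
person_stream <- function(pid, rx_days, codes, meas_days, meas_vals) {
  list(
    prescriptions = prescription_records(rep(pid, length(rx_days)), rx_days,
                                         codes,
                                         description = ""),
    measures = measure_records(rep(pid, length(meas_days)), meas_days, "LDL",
                               meas_vals, "mmol_per_L")
  )
}

# Six persons engineered to fail one QC stage each, in cascade order:
# comed, baseline/post measures, prior record, rx after post, drug change,
# regularity. Treatment start is day 1000 for everyone.
qc_fixture <- function() {
  refill7 <- seq(1000, 1366, by = 61)   # regular refills through the post date
  streams <- list(
    person_stream("p1", c(refill7, 1100), c(rep("SIMVA40", 7), "EZET10"),
                  c(100, 950, 1300), c(3.2, 3.0, 2.5)),
    person_stream("p2", refill7, rep("SIMVA40", 7),
                  c(100, 950), c(3.2, 3.0)),
    person_stream("p3", refill7, rep("SIMVA40", 7),
                  c(950, 1300), c(3.0, 2.5)),
    person_stream("p4", c(1000, 1061), rep("SIMVA40", 2),
                  c(100, 950, 1300), c(3.2, 3.0, 2.5)),
    person_stream("p5", c(1000, 1061, 1122, 1183, 1244, 1305, 1366),
                  c(rep("SIMVA40", 3), rep("ATORV40", 4)),
                  c(100, 950, 1300), c(3.2, 3.0, 2.5)),
    person_stream("p6", c(1000, 1400), rep("SIMVA40", 2),
                  c(100, 950, 1300), c(3.2, 3.0, 2.5))
  )
  list(
    measures = do.call(rbind, lapply(streams, `[[`, "measures")),
    prescriptions = do.call(rbind, lapply(streams, `[[`, "prescriptions")),
    map = default_code_map(),
    scenario = scenario_config(mode = "lenient", measure_mode = "average",
                               min_cohort_size = 1L, min_drug_group_size = 1L)
  )
}

# A fully QC-clean statin user (regular refills, old record, good baseline)
clean_person <- function(pid = "ok1", baseline_value = 3.0) {
  person_stream(pid, seq(1000, 1366, by = 61), rep("SIMVA40", 7),
                c(100, 950, 1300), c(3.2, baseline_value, 2.5))
}

# Small random EHR bundle for property-style cascade tests
random_bundle <- function(n = 300, seed = 1) {
  params <- generative_params(
    variants = variant_panel(c("v1", "v2"), maf = c(0.3, 0.2),
                             beta0 = c(0.3, 0), gammaD = c(0.1, 0)),
    intercept = 4, betaD = -1,
    var_env_persistent = 0.25, var_env_occasion = 0.25)
  behavior <- rx_behavior(regularity = 0.75, p_same_class_comed = 0.15,
                          p_combo = 0.1, p_switch = 0.2)
  simulate_ehr(n, params, behavior, seed = seed)
}

expect_within_3se <- function(estimate, target, se) {
  expect_lt(abs(estimate - target), 3 * se)
}
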