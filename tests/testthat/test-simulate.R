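test_that("genotype sampling matches its binomial and Hardy-Weinberg oracles", {
  n <- 10000
  params <- generative_params(variants = variant_panel("v1", maf = 0.3))
  pop <- simulate_population(n, params, seed = 11)
  # empirical allele frequency within 3 binomial SE of the maf
  expect_within_3se(mean(pop$dosages[, 1]) / 2, 0.3,
                    sqrt(0.3 * 0.7 / (2 * n)))

  # maf = 0.5: genotype frequencies near (0.25, 0.5, 0.25)
  pop5 <- simulate_population(n, generative_params(
    variants = variant_panel("v1", maf = 0.5)), seed = 12)
  freq <- tabulate(pop5$dosages[, 1] + 1, 3) / n
  for (k in 1:3)
    expect_within_3se(freq[k], c(0.25, 0.5, 0.25)[k],
                      sqrt(freq[k] * (1 - freq[k]) / n))

  # determinism and maf validation
  pop2 <- simulate_population(n, params, seed = 11)
  expect_identical(pop$dosages, pop2$dosages)
  expect_error(variant_panel("v1", maf = 0.7), "maf")
})

test_that("trajectories evaluate the longitudinal model exactly", {
  panel <- variant_panel("v1", maf = 0.3, beta0 = 1, gammaD = 0)
  person <- list(person_id = "a", sex = 0, age_decades = 0,
                 env_persistent = 0, prs_latent = 0)

  # degenerate model: every measure equals the intercept
  p0 <- generative_params(variants = variant_panel("v1", maf = 0.3),
                          intercept = 4, betaD = 0, betaE = 0,
                          var_env_persistent = 0, var_env_occasion = 0)
  tr <- simulate_trajectory(person, dosage = 1, p0, dates = c(0L, 100L, 500L),
                            drug_start = 200L, seed = 1)
  expect_equal(tr$value, rep(4, 3))

  # baseline genetic effect only: dosage 2, beta0 = 1 shifts all measures by 2
  p1 <- generative_params(variants = panel, intercept = 0, betaD = 0,
                          betaE = 0, var_env_persistent = 0,
                          var_env_occasion = 0)
  tr <- simulate_trajectory(person, dosage = 2, p1, dates = c(0L, 500L),
                            drug_start = 200L, seed = 1)
  expect_equal(tr$value, c(2, 2))

  # drug effect switches on at the start date
  p2 <- generative_params(variants = variant_panel("v1", maf = 0.3),
                          intercept = 4, betaD = -1, betaE = 0,
                          var_env_persistent = 0, var_env_occasion = 0)
  tr <- simulate_trajectory(person, dosage = 0, p2, dates = c(0L, 199L, 200L, 500L),
                            drug_start = 200L, seed = 1)
  expect_equal(tr$value, c(4, 4, 3, 3))
})

test_that("generated records are reproduced by re-evaluating the model formula", {
  panel <- variant_panel(c("v1", "v2"), maf = c(0.3, 0.4),
                         beta0 = c(0.5, -0.2), gammaD = c(0.1, 0))
  params <- generative_params(variants = panel, intercept = 4, betaD = -1,
                              betaE = 0.8, var_env_persistent = 0.3,
                              var_env_occasion = 0.2, sex_effect = 0.2,
                              age_effect = 0.1)
  person <- list(person_id = "a", sex = 1, age_decades = 0.5,
                 env_persistent = 0.7, prs_latent = 0)
  g <- c(2, 1)
  dates <- c(0L, 300L, 900L)
  tr <- simulate_trajectory(person, g, params, dates, drug_start = 400L,
                            seed = 9)
  occ <- attr(tr, "occasion")
  drug <- as.numeric(dates >= 400L)
  manual <- 4 + sum(c(0.5, -0.2) * g) + 0.8 * 0.7 +
    drug * (-1 + sum(c(0.1, 0) * g)) + 0.2 * 1 + 0.1 * 0.5 + occ
  expect_equal(tr$value, manual, tolerance = 1e-12)
})

test_that("prescription streams follow the schedule, thinning and event flags", {
  map <- default_code_map()

  # full regularity: refills at exactly days 0, 61, ..., 610
  rx <- simulate_prescriptions("a", 0L, rx_behavior(regularity = 1,
                                                    p_same_class_comed = 0,
                                                    p_combo = 0, p_switch = 0),
                               map, horizon_days = 610L, seed = 1)
  expect_identical(rx$date, seq(0L, 610L, by = 61L))
  expect_identical(nrow(rx), 11L)
  # description embeds the drug name and a parseable dose
  expect_true(all(grepl("[0-9]+mg", rx$description)))

  # forced combination products resolve to is_combination codes
  rxc <- simulate_prescriptions("a", 0L, rx_behavior(p_combo = 1,
                                                     p_same_class_comed = 0,
                                                     p_switch = 0),
                                map, horizon_days = 300L, seed = 2)
  info <- map[match(rxc$code, map$code), ]
  expect_true(all(info$is_combination))

  # binomial thinning: regularity 0.5 realizes about half the scheduled refills
  beh <- rx_behavior(regularity = 0.5, p_same_class_comed = 0, p_combo = 0,
                     p_switch = 0)
  counts <- vapply(1:400, function(i)
    nrow(simulate_prescriptions("a", 0L, beh, map, horizon_days = 610L,
                                seed = i)), numeric(1))
  # first refill always occurs; the other 10 are kept w.p. 0.5
  expected <- 1 + 10 * 0.5
  mc_se <- sqrt(10 * 0.25 / 400)
  expect_within_3se(mean(counts), expected, mc_se)
})

test_that("drug-naive controls obey spacing bounds and the no-treatment null", {
  params <- generative_params(
    variants = variant_panel("v1", maf = 0.3, beta0 = 0.6),
    intercept = 4, betaD = -1, var_env_persistent = 0.25,
    var_env_occasion = 0.25)
  ctl <- simulate_controls(4000, params, seed = 21)
  n <- 4000
  sp <- ctl$measures$date[(n + 1):(2 * n)] - ctl$measures$date[1:n]
  expect_true(all(sp >= 183 & sp <= 1095))

  # no genetic effect on change without treatment, despite beta0 != 0
  dy <- ctl$measures$value[(n + 1):(2 * n)] - ctl$measures$value[1:n]
  fit <- variant_association(dy, ctl$dosages[, 1], model = "control_change")
  expect_within_3se(fit$beta, 0, fit$se)

  # degenerate model: both measures identical
  p0 <- generative_params(variants = variant_panel("v1", maf = 0.3),
                          intercept = 4, betaD = 0, betaE = 0,
                          var_env_persistent = 0, var_env_occasion = 0)
  ctl0 <- simulate_controls(50, p0, seed = 3)
  expect_equal(ctl0$measures$value[1:50], ctl0$measures$value[51:100])
})

test_that("the polygenic background correlates with baseline as the variances imply", {
  v_prs <- 0.3
  params <- generative_params(variants = variant_panel("v1", maf = 0.3),
                              intercept = 4, betaD = 0, betaE = 1,
                              var_env_persistent = 0.2,
                              var_env_occasion = 0.25,
                              prs_arch = list(var = v_prs))
  n <- 20000
  ctl <- simulate_controls(n, params, seed = 77)
  y0 <- ctl$measures$value[1:n]
  prs <- ctl$persons$prs_latent
  var_g <- 0.3^2 * 0  # beta0 = 0: no variant contribution to baseline
  expected_cor <- sqrt(v_prs / (v_prs + 0.2 + 0.25 + var_g))
  expect_within_3se(cor(prs, y0), expected_cor, 1 / sqrt(n))
})

test_that("the bulk prescription generator matches the per-person schedule rules", {
  map <- default_code_map()
  beh <- rx_behavior(regularity = 1, p_same_class_comed = 0, p_combo = 0,
                     p_switch = 0)
  rx <- pgxresponse:::simulate_rx_bundle(c("a", "b"), c(0L, 100L), beh, map,
                                         horizon_days = 305L, seed = 5)
  expect_identical(rx$date[rx$person_id == "a"], seq(0L, 305L, by = 61L))
  expect_identical(rx$date[rx$person_id == "b"], seq(100L, 405L, by = 61L))
  expect_identical(length(unique(rx$code[rx$person_id == "a"])), 1L)
})
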