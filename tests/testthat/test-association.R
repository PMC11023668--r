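simulate_change_cohort <- function(n, beta0, gammaD, maf = 0.3,
                                   var_p = 0.25, var_o = 0.25, betaD = -1,
                                   seed = 1) {
  set.seed(seed)
  g <- rbinom(n, 2L, maf)
  P <- rnorm(n, 0, sqrt(var_p))
  e0 <- rnorm(n, 0, sqrt(var_o))
  e1 <- rnorm(n, 0, sqrt(var_o))
  list(g = g, y0 = beta0 * g + P + e0,
       dy = betaD + gammaD * g + e1 - e0)
}

test_that("the unadjusted change-score estimator recovers the pharmacogenetic effect", {
  # no baseline effect
  d <- simulate_change_cohort(10000, beta0 = 0, gammaD = 0.2, seed = 31)
  fit <- variant_association(d$dy, d$g, model = "unadjusted")
  expect_within_3se(fit$beta, 0.2, fit$se)

  # the baseline effect cancels in the difference
  d2 <- simulate_change_cohort(10000, beta0 = 0.8, gammaD = 0.2, seed = 32)
  fit2 <- variant_association(d2$dy, d2$g, model = "unadjusted")
  expect_within_3se(fit2$beta, 0.2, fit2$se)
  expect_identical(fit2$flag, "ok")
  expect_identical(fit2$n, 10000L)
})

test_that("monomorphic dosages are flagged and never fitted", {
  fit <- variant_association(rnorm(50), rep(2, 50), model = "unadjusted")
  expect_identical(fit$flag, "monomorphic")
  expect_true(is.na(fit$beta) && is.na(fit$p))
})

test_that("flipping the counted allele flips the effect sign exactly", {
  d <- simulate_change_cohort(2000, beta0 = 0, gammaD = 0.15, seed = 33)
  f1 <- variant_association(d$dy, d$g, model = "unadjusted")
  f2 <- variant_association(d$dy, 2 - d$g, model = "unadjusted")
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-12)
  expect_equal(f2$se, f1$se, tolerance = 1e-12)
  expect_equal(f2$eaf, 1 - f1$eaf, tolerance = 1e-12)
})

test_that("scans emit one deterministic row per variant, model and mode", {
  set.seed(40)
  n <- 400
  G <- matrix(rbinom(n * 5, 2, 0.3), n, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  responses <- list(absolute = rnorm(n), log_relative = rnorm(n))
  base <- rnorm(n)
  tab <- scan_variants(responses, G, baseline = base,
                       models = c("unadjusted", "baseline_adjusted"))
  expect_identical(nrow(tab), 20L)  # 5 variants x 2 models x 2 modes
  expect_identical(tab, scan_variants(responses, G, baseline = base,
                                      models = c("unadjusted",
                                                 "baseline_adjusted")))
  # the partitioned-regression scan equals a full lm fit
  ref <- summary(lm(responses$absolute ~ G[, 2] + base))$coefficients[2, ]
  row <- tab[tab$variant_id == "v2" & tab$model == "baseline_adjusted" &
               tab$mode == "absolute", ]
  expect_equal(row$beta, ref[["Estimate"]], tolerance = 1e-10)
  expect_equal(row$se, ref[["Std. Error"]], tolerance = 1e-10)
  expect_equal(row$p, ref[["Pr(>|t|)"]], tolerance = 1e-8)
})

test_that("Bonferroni thresholds and counting utilities match their closed forms", {
  expect_equal(signif(bonferroni_threshold(0.05, 7), 3), 0.00714)
  expect_equal(signif(bonferroni_threshold(0.05, 18983), 3), 2.63e-06)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")

  expect_identical(count_below(numeric(0), 0.05), 0L)
  expect_identical(directional_concordance(c(1, -1), c(1, 1)), 1L)
  expect_identical(directional_concordance(numeric(0), numeric(0)), 0L)
  expect_warning(out <- directional_concordance(c(0, 1), c(1, 1)), "zero")
  expect_identical(out, 1L)
})

test_that("genotype-stratified summaries reproduce the baseline-adjustment artifact", {
  set.seed(50)
  n <- 8000L
  make_group <- function(beta0, betaD) {
    g <- rbinom(n, 2, 0.3)
    sex <- rbinom(n, 1, 0.5); age <- rnorm(n)
    P <- rnorm(n, 0, 0.5)
    y0 <- 4 + beta0 * g + 0.2 * sex + 0.1 * age + P + rnorm(n, 0, 0.5)
    dy <- betaD + rnorm(n, 0, 0.5) - (y0 - (4 + beta0 * g + 0.2 * sex +
                                              0.1 * age + P))
    list(baseline = y0, change = dy, dosage = g,
         covariates = cbind(sex = sex, age = age))
  }
  trt <- make_group(beta0 = 0.5, betaD = -1)
  ctl <- make_group(beta0 = 0.5, betaD = 0)
  s <- genotype_stratified_summary(trt, ctl)

  # cell sizes partition each group
  for (gr in c("treated", "control"))
    for (oc in unique(s$outcome))
      expect_identical(sum(s$n[s$group == gr & s$outcome == oc]), n)

  base_t <- s[s$group == "treated" & s$outcome == "baseline", ]
  expect_true(all(diff(base_t$mean) > 0))  # baseline rises with genotype

  # unadjusted change flat; baseline-adjusted change sloped in BOTH groups
  slope <- function(gr, oc) {
    z <- s[s$group == gr & s$outcome == oc, ]
    coef(lm(z$mean ~ z$genotype, weights = z$n))[[2]]
  }
  expect_lt(abs(slope("treated", "change_unadjusted")), 0.05)
  expect_lt(abs(slope("control", "change_unadjusted")), 0.05)
  expect_gt(abs(slope("treated", "change_adjusted")), 0.1)
  expect_gt(abs(slope("control", "change_adjusted")), 0.1)

  # null generator: change cells are flat everywhere
  trt0 <- make_group(beta0 = 0, betaD = -1)
  ctl0 <- make_group(beta0 = 0, betaD = 0)
  s0 <- genotype_stratified_summary(trt0, ctl0)
  ch <- s0[s0$outcome != "baseline", ]
  expect_lt(max(abs(ch$mean)), 3 * max(ch$sd / sqrt(ch$n)))
})
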