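# Baseline-adjustment bias, in closed form and by simulation.
#
# Under the longitudinal model the observed baseline and change are
#   Y0     = beta0*G + P + e0           Var(P) = var_persistent
#   DeltaY = betaD + gammaD*G + e1 - e0 Var(e_t) = var_occasion
# with G the allele dosage (Var(G) = var_g = 2*maf*(1-maf)) and P every
# component shared by both timepoints (persistent environment, polygenic
# background, other variants). The population coefficient on G in the joint
# least-squares of DeltaY on (G, Y0) solves the 2x2 normal equations
#   [ var_g          beta0*var_g              ] [bG ]   [ gammaD*var_g            ]
#   [ beta0*var_g    beta0^2*var_g + vp + vo  ] [bY0] = [ gammaD*beta0*var_g - vo ]
# giving
#   E[b_adj] = gammaD + beta0 * vo / (vp + vo).
# The bias term beta0*vo/(vp+vo) vanishes at beta0 = 0 and as vo -> 0, and is
# linear in beta0, so the spurious association signal (the squared
# standardized effect, i.e. the test's non-centrality per observation) grows
# quadratically in beta0. The unadjusted estimator is unbiased for gammaD at
# every parameter value since Cov(G, DeltaY) = gammaD*var_g.

#' Parameters of the baseline-adjustment bias model
#'
#' @param beta0 baseline genetic effect of the focal variant.
#' @param gammaD pharmacogenetic effect of the focal variant.
#' @param betaD mean drug effect (does not enter the coefficients).
#' @param maf minor allele frequency; `var_g = 2*maf*(1-maf)`.
#' @param var_persistent variance of all baseline components shared across
#'   both timepoints (persistent environment including its effect scaling,
#'   polygenic background, other variants).
#' @param var_occasion occasion noise variance per timepoint.
#' @return list of class `bias_model_params`.
#' @export
bias_model_params <- function(beta0, gammaD = 0, betaD = -1, maf = 0.3,
                              var_persistent = 0.5, var_occasion = 0.5) {
  if (var_persistent < 0 || var_occasion < 0) stop("variances must be >= 0")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  var_g <- 2 * maf * (1 - maf)
  structure(list(beta0 = beta0, gammaD = gammaD, betaD = betaD, maf = maf,
                 var_g = var_g, var_persistent = var_persistent,
                 var_occasion = var_occasion),
            class = "bias_model_params")
}

#' Map generative parameters to bias-model parameters for one variant
#'
#' Folds the persistent environment (scaled by its effect), the polygenic
#' background and all other variants' baseline contributions into
#' `var_persistent`.
#'
#' @param params a [generative_params()] with `gammaE = 0`.
#' @param variant index or id of the focal variant.
#' @return a [bias_model_params()].
#' @export
bias_params_from_generative <- function(params, variant = 1L) {
  if (params$gammaE != 0)
    stop("closed-form bias theory assumes gammaE = 0")
  vp <- params$variants
  i <- if (is.character(variant)) match(variant, vp$variant_id) else variant
  others <- setdiff(seq_len(nrow(vp)), i)
  var_pers <- params$betaE^2 * params$var_env_persistent +
    sum(vp$beta0[others]^2 * 2 * vp$maf[others] * (1 - vp$maf[others])) +
    if (!is.null(params$prs_arch)) params$prs_arch$var else 0
  bias_model_params(beta0 = vp$beta0[i], gammaD = vp$gammaD[i],
                    betaD = params$betaD, maf = vp$maf[i],
                    var_persistent = var_pers,
                    var_occasion = params$var_env_occasion)
}

#' Expected baseline-adjusted genetic effect estimate (closed form)
#'
#' Population coefficient on the dosage in the joint least-squares of the
#' biomarker difference on (dosage, baseline):
#' `gammaD + beta0 * var_occasion / (var_persistent + var_occasion)`.
#'
#' @param params a [bias_model_params()].
#' @return numeric scalar.
#' @export
expected_adjusted_estimate <- function(params) {
  tot <- params$var_persistent + params$var_occasion
  if (tot <= 0) {
    if (params$beta0^2 * params$var_g <= 0)
      stop("degenerate model: baseline has zero variance")
    stop("degenerate model: baseline collinear with dosage")
  }
  params$gammaD + params$beta0 * params$var_occasion / tot
}

#' Expected association statistic of the baseline-adjusted test
#'
#' Squared standardized effect of the adjusted estimator (the test's
#' non-centrality for `n` observations): `b_adj^2 / Var_n(b_adj)` with the
#' population residual variance of the joint fit.
#'
#' @param params a [bias_model_params()].
#' @param n number of observations.
#' @return numeric scalar.
#' @export
expected_adjusted_stat <- function(params, n = 1) {
  vg <- params$var_g; vp <- params$var_persistent; vo <- params$var_occasion
  b <- expected_adjusted_estimate(params)
  var_y0 <- params$beta0^2 * vg + vp + vo
  det <- vg * (vp + vo)
  # population residual variance of DeltaY | (G, Y0)
  cvec <- c(params$gammaD * vg, params$gammaD * params$beta0 * vg - vo)
  Sigma <- matrix(c(vg, params$beta0 * vg, params$beta0 * vg, var_y0), 2)
  resid <- params$gammaD^2 * vg + 2 * vo -
    drop(t(cvec) %*% solve(Sigma, cvec))
  if (resid <= 1e-12) return(if (b == 0) 0 else Inf)
  n * b^2 * det / (var_y0 * resid)
}

# single Monte-Carlo replicate: joint OLS of DeltaY on (G, Y0); returns the
# dosage coefficient and its SE
simulate_adjusted_fit <- function(params, n) {
  g <- stats::rbinom(n, 2L, params$maf)
  P <- stats::rnorm(n, 0, sqrt(params$var_persistent))
  e0 <- stats::rnorm(n, 0, sqrt(params$var_occasion))
  e1 <- stats::rnorm(n, 0, sqrt(params$var_occasion))
  y0 <- params$beta0 * g + P + e0
  dy <- params$betaD + params$gammaD * g + e1 - e0
  fit <- stats::lm.fit(cbind(1, g, y0), dy)
  rss <- sum(fit$residuals^2)
  xtx_inv <- chol2inv(fit$qr$qr[1:3, 1:3, drop = FALSE])
  se <- sqrt(rss / (n - 3) * xtx_inv[2, 2])
  c(beta = unname(fit$coefficients[2]), se = se)
}

#' Bias curve over a grid of baseline effects
#'
#' For each `beta0` on the grid: the closed-form expected adjusted estimate,
#' the simulated mean estimate with its Monte-Carlo standard error, and the
#' expected association statistic (squared standardized effect).
#'
#' @param beta0_grid numeric grid (a symmetric grid around 0 is recommended).
#' @param params a [bias_model_params()]; its `beta0` is overridden per point.
#' @param n_per_rep observations per simulated replicate.
#' @param reps replicates per grid point (>= 2).
#' @param seed integer seed.
#' @return data.frame of class `bias_curve`.
#' @export
bias_curve <- function(beta0_grid, params, n_per_rep = 10000L, reps = 20L,
                       seed = 1L) {
  if (reps < 2L) stop("reps must be >= 2")
  set.seed(derive_seed(seed, 41L))
  rows <- lapply(beta0_grid, function(b0) {
    p <- params; p$beta0 <- b0
    sims <- replicate(reps, simulate_adjusted_fit(p, n_per_rep)["beta"])
    data.frame(beta0 = b0,
               expected = expected_adjusted_estimate(p),
               simulated_mean = mean(sims),
               mc_se = stats::sd(sims) / sqrt(reps),
               expected_stat = expected_adjusted_stat(p, n_per_rep))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bias_curve", "data.frame")
  out
}

#' @export
print.bias_curve <- function(x, ...) {
  cat("Baseline-adjustment bias curve (closed form vs Monte Carlo)\n")
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' @export
plot.bias_curve <- function(x, ...) {
  graphics::plot(x$beta0, x$expected, type = "l",
                 xlab = expression(beta[0]),
                 ylab = "expected adjusted estimate", ...)
  graphics::arrows(x$beta0, x$simulated_mean - 3 * x$mc_se,
                   x$beta0, x$simulated_mean + 3 * x$mc_se,
                   length = 0.02, angle = 90, code = 3, col = "grey40")
  graphics::points(x$beta0, x$simulated_mean, pch = 19)
  invisible(x)
}

#' Power-law exponent of the spurious association signal in |beta0|
#'
#' Fits `log(stat) ~ log(|beta0|)` over the non-zero grid points; under the
#' model the signal grows quadratically near 0 (exponent 2).
#'
#' @param curve a [bias_curve()].
#' @return fitted exponent (slope of the log-log fit).
#' @export
power_law_exponent <- function(curve) {
  keep <- curve$beta0 != 0 & curve$expected_stat > 0
  if (sum(keep) < 2L) stop("need >= 2 non-zero grid points")
  stats::coef(stats::lm(log(curve$expected_stat[keep]) ~
                          log(abs(curve$beta0[keep]))))[[2]]
}

#' Negative-control signature of baseline adjustment
#'
#' Simulates a treated and a drug-naive control group under the additive
#' model with `gammaD = 0` and a non-zero baseline effect, and fits the
#' change-score regression unadjusted and baseline-adjusted in both groups.
#' The expected pattern: null association in both unadjusted analyses, and
#' the SAME spurious coefficient `beta0 * vo / (vp + vo)` in both adjusted
#' analyses.
#'
#' @param params a [bias_model_params()].
#' @param n persons per group.
#' @param seed integer seed.
#' @return data.frame with one row per group x model: `beta`, `se`, `p`.
#' @export
control_signature <- function(params, n = 20000L, seed = 1L) {
  set.seed(derive_seed(seed, 42L))
  fit_group <- function(p) {
    g <- stats::rbinom(n, 2L, p$maf)
    P <- stats::rnorm(n, 0, sqrt(p$var_persistent))
    e0 <- stats::rnorm(n, 0, sqrt(p$var_occasion))
    e1 <- stats::rnorm(n, 0, sqrt(p$var_occasion))
    y0 <- p$beta0 * g + P + e0
    dy <- p$betaD + p$gammaD * g + e1 - e0
    rbind(variant_association(dy, g, model = "unadjusted"),
          variant_association(dy, g, baseline = y0,
                              model = "baseline_adjusted"))
  }
  treated <- fit_group(params)
  ctrl_p <- params; ctrl_p$betaD <- 0; ctrl_p$gammaD <- 0
  controls <- fit_group(ctrl_p)
  controls$model <- sub("unadjusted", "control_change", controls$model)
  controls$model <- sub("baseline_adjusted", "control_change_adjusted",
                        controls$model)
  out <- rbind(cbind(group = "treated", treated),
               cbind(group = "control", controls))
  attr(out, "expected_adjusted") <- expected_adjusted_estimate(
    within_params(params, gammaD = 0))
  out
}

within_params <- function(p, ...) { mods <- list(...); p[names(mods)] <- mods; p }

#' Sign-reversal demonstration for polygenic scores
#'
#' Generates a treated and a control population in which a polygenic score
#' raises the baseline biomarker level and the drug acts multiplicatively
#' (log-scale effect), then regresses the absolute response on the
#' standardized score, unadjusted and baseline-adjusted, in both groups.
#' Under this generator higher scores produce a LARGER absolute reduction
#' (negative unadjusted coefficient in the treated), while baseline
#' adjustment reverses the sign; drug-naive controls show no unadjusted
#' association but the same artifactual positive coefficient when adjusted.
#'
#' @param n persons per group.
#' @param params a log-scale [generative_params()] with a `prs_arch`;
#'   defaults emulate a statin-like 35% biomarker reduction.
#' @param schedule a [visit_schedule()].
#' @param seed integer seed.
#' @return list of class `sign_reversal` with the four fits and the
#'   generator settings.
#' @export
sign_reversal_demo <- function(n = 20000L,
                               params = generative_params(
                                 variants = variant_panel("v1", maf = 0.3),
                                 intercept = log(3.5), scale = "log",
                                 betaD = log(0.65), betaE = 1,
                                 var_env_persistent = 0.02,
                                 var_env_occasion = 0.015,
                                 prs_arch = list(var = 0.03)),
                               schedule = visit_schedule(), seed = 1L) {
  if (params$scale != "log")
    stop("the sign-reversal demonstration requires a multiplicative ",
         "(log-scale) drug effect")
  has_prs <- !is.null(params$prs_arch) && params$prs_arch$var > 0

  ctl <- simulate_controls(n, params, schedule, seed = derive_seed(seed, 51L))
  trt_pop <- simulate_population(n, params, derive_seed(seed, 52L))
  set.seed(derive_seed(seed, 53L))
  mu <- trajectory_mean(params, trt_pop$dosages,
                        trt_pop$persons$env_persistent, drug = 0,
                        prs_latent = trt_pop$persons$prs_latent)
  y0_t <- exp(mu + stats::rnorm(n, 0, sqrt(params$var_env_occasion)))
  y1_t <- exp(mu + params$betaD +
                drop(trt_pop$dosages %*% params$variants$gammaD) +
                stats::rnorm(n, 0, sqrt(params$var_env_occasion)))

  prs_t <- standardize(trt_pop$persons$prs_latent, allow_constant = !has_prs)
  prs_c <- standardize(ctl$persons$prs_latent, allow_constant = !has_prs)
  dy_t <- y1_t - y0_t
  dy_c <- ctl$measures$value[(n + 1):(2 * n)] - ctl$measures$value[1:n]
  y0_c <- ctl$measures$value[1:n]

  fits <- rbind(
    cbind(group = "treated",
          variant_association(dy_t, prs_t, model = "unadjusted",
                              variant_id = "PRS")),
    cbind(group = "treated",
          variant_association(dy_t, prs_t, baseline = y0_t,
                              model = "baseline_adjusted", variant_id = "PRS")),
    cbind(group = "control",
          variant_association(dy_c, prs_c, model = "control_change",
                              variant_id = "PRS")),
    cbind(group = "control",
          variant_association(dy_c, prs_c, baseline = y0_c,
                              model = "control_change_adjusted",
                              variant_id = "PRS"))
  )
  structure(list(fits = fits, betaD = params$betaD, n = n,
                 prs_var = if (has_prs) params$prs_arch$var else 0),
            class = "sign_reversal")
}

standardize <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (s == 0) {
    if (allow_constant) return(x - mean(x))
    stop("cannot standardize a constant score")
  }
  (x - mean(x)) / s
}

#' @export
print.sign_reversal <- function(x, ...) {
  cat(sprintf("Sign-reversal demonstration (n = %d per group, drug effect = %.1f%%)\n",
              x$n, 100 * (exp(x$betaD) - 1)))
  print.data.frame(x$fits[, c("group", "model", "beta", "se", "p")],
                   digits = 3, row.names = FALSE)
  cat("Expected pattern: treated unadjusted < 0, treated adjusted > 0,\n",
      "control unadjusted ~ 0, control adjusted > 0.\n", sep = "")
  invisible(x)
}
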