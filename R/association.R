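# Per-variant association of drug-response phenotypes.
#
# The estimand is the pharmacogenetic effect gammaD: because the change score
# Delta Y = betaD + gammaD*G + delta is free of the baseline genetic effect,
# the correct model regresses the (covariate-adjusted) difference on dosage
# WITHOUT baseline adjustment. The baseline_adjusted variant (appending the
# baseline level to the covariates) is provided to quantify the bias it
# induces; control_change applies the same two models to the longitudinal
# change of drug-naive persons (negative control).

#' Association of a response with a single variant
#'
#' Ordinary least squares of `response` on the allele dosage plus covariates
#' (plus the baseline level when `model = "baseline_adjusted"` or
#' `"control_change_adjusted"`). Two-sided p-value from the t distribution
#' with residual degrees of freedom.
#'
#' @param response numeric outcome vector.
#' @param dosage allele dosage in \[0, 2\].
#' @param covariates optional numeric matrix.
#' @param baseline baseline levels; required for the adjusted model variants.
#' @param model one of `"unadjusted"`, `"baseline_adjusted"`,
#'   `"control_change"`, `"control_change_adjusted"`.
#' @param variant_id label carried into the result.
#' @return one-row data.frame: `variant_id, model, beta, se, p, n, eaf,
#'   flag` (`"ok"`, `"monomorphic"` or `"n_too_small"`).
#' @export
variant_association <- function(response, dosage, covariates = NULL,
                                baseline = NULL,
                                model = c("unadjusted", "baseline_adjusted",
                                          "control_change",
                                          "control_change_adjusted"),
                                variant_id = "v") {
  model <- match.arg(model)
  adjusted <- model %in% c("baseline_adjusted", "control_change_adjusted")
  if (adjusted) {
    if (is.null(baseline)) stop("baseline required for adjusted model variants")
    covariates <- cbind(covariates, baseline = baseline)
  }
  res <- ols_scan(response, matrix(dosage, ncol = 1,
                                   dimnames = list(NULL, variant_id)),
                  covariates)
  data.frame(variant_id = variant_id, model = model,
             beta = res$beta, se = res$se, p = res$p, n = res$n,
             eaf = res$eaf, flag = res$flag, stringsAsFactors = FALSE)
}

# Exact OLS per dosage column via partitioned regression: y and each dosage
# column are residualized on [1, covariates] once, then the slope, its SE and
# t-test are computed with residual df n - p - 1 (identical to the full fit).
ols_scan <- function(y, G, covariates = NULL) {
  stopifnot(length(y) == nrow(G))
  n <- length(y)
  X <- cbind(rep(1, n), covariates)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    X <- X[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
    qr_x <- qr(X)
  }
  p <- ncol(X)
  yr <- qr.resid(qr_x, y)
  Gr <- qr.resid(qr_x, G)
  sgg <- colSums(Gr^2)
  mono <- apply(G, 2, function(g) stats::var(g) == 0)
  df <- n - p - 1L
  flag <- ifelse(mono, "monomorphic", ifelse(df < 1L, "n_too_small", "ok"))
  beta <- colSums(Gr * yr) / sgg
  ssr <- sum(yr^2) - beta^2 * sgg
  sigma2 <- ssr / df
  se <- sqrt(sigma2 / sgg)
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  bad <- flag != "ok"
  beta[bad] <- NA_real_; se[bad] <- NA_real_; pval[bad] <- NA_real_
  list(variant_id = colnames(G), beta = unname(beta), se = unname(se),
       p = unname(pval), n = n, eaf = unname(colMeans(G) / 2), flag = unname(flag))
}

#' Per-variant association scan over a dosage panel
#'
#' One result row per variant x model variant x response mode, ordered by
#' variant then model then mode.
#'
#' @param responses named list of response vectors (e.g.
#'   `list(absolute = ..., log_relative = ...)`).
#' @param dosages persons x variants dosage matrix, rows aligned with the
#'   responses.
#' @param covariates optional covariate matrix.
#' @param baseline baseline levels (needed for adjusted models).
#' @param models character vector of model variants to fit.
#' @return data.frame of class `pgx_scan` with columns
#'   `variant_id, model, mode, beta, se, p, n, eaf, flag`.
#' @export
scan_variants <- function(responses, dosages, covariates = NULL,
                          baseline = NULL, models = c("unadjusted",
                                                      "baseline_adjusted")) {
  if (!is.list(responses)) responses <- list(response = responses)
  out <- list()
  for (model in models) {
    adjusted <- model %in% c("baseline_adjusted", "control_change_adjusted")
    cov_m <- if (adjusted) {
      if (is.null(baseline)) stop("baseline required for adjusted model variants")
      cbind(covariates, baseline = baseline)
    } else covariates
    for (mode in names(responses)) {
      y <- responses[[mode]]
      res <- ols_scan(y, dosages, cov_m)
      out[[paste(model, mode)]] <- data.frame(
        variant_id = res$variant_id, model = model, mode = mode,
        beta = res$beta, se = res$se, p = res$p, n = res$n, eaf = res$eaf,
        flag = res$flag, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab$variant_id, tab$model, tab$mode), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("pgx_scan", "data.frame")
  tab
}

#' @export
print.pgx_scan <- function(x, digits = 4, ...) {
  cat(sprintf("Variant association scan: %d variants, %d rows (n = %d)\n",
              length(unique(x$variant_id)), nrow(x), x$n[1]))
  print.data.frame(x, digits = digits, row.names = FALSE, ...)
  invisible(x)
}

#' @export
summary.pgx_scan <- function(object, alpha = 5e-8, ...) {
  hits <- object[!is.na(object$p) & object$p < alpha, , drop = FALSE]
  cat(sprintf("%d of %d tests below p < %.3g\n", nrow(hits), nrow(object), alpha))
  if (nrow(hits) > 0L) print.data.frame(hits, digits = 4, row.names = FALSE)
  invisible(hits)
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m number of tests, at least 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Count p-values below a threshold
#'
#' @param p_values numeric vector of p-values.
#' @param threshold significance threshold.
#' @return integer count of values strictly below `threshold`.
#' @export
count_below <- function(p_values, threshold) {
  if (length(p_values) == 0L) return(0L)
  stopifnot(all(is.finite(p_values)), all(p_values > 0 & p_values <= 1))
  sum(p_values < threshold)
}

#' Count directionally concordant effect pairs
#'
#' @param discovery,replication aligned effect-size vectors.
#' @param mask logical vector selecting the pairs to count.
#' @return integer count of masked pairs with identical sign; a zero effect
#'   counts as discordant (with a warning).
#' @export
directional_concordance <- function(discovery, replication,
                                    mask = rep(TRUE, length(discovery))) {
  stopifnot(length(discovery) == length(replication))
  d <- discovery[mask]; r <- replication[mask]
  if (length(d) == 0L) return(0L)
  if (any(d == 0 | r == 0))
    warning("zero effect size counted as discordant", call. = FALSE)
  sum(sign(d) == sign(r) & d != 0 & r != 0)
}

#' Genotype-stratified summary of baseline and change phenotypes
#'
#' For drug-naive controls and treated persons, summarizes the standardized,
#' sex-and-age-adjusted baseline level and change phenotype per rounded
#' genotype (0/1/2), once without and once with baseline adjustment of the
#' change.
#'
#' @param treated list with `baseline`, `change`, `dosage`, and a `covariates`
#'   matrix (sex, age).
#' @param controls same structure for drug-naive persons.
#' @return data.frame (class `genotype_strata`): one row per group x outcome x
#'   genotype with `mean`, `sd`, `n`.
#' @export
genotype_stratified_summary <- function(treated, controls) {
  one_group <- function(g, label) {
    geno <- round(g$dosage)
    std <- function(v) { r <- adjust_covariates(v, g$covariates); r / stats::sd(r) }
    outcomes <- list(
      baseline = std(g$baseline),
      change_unadjusted = std(g$change),
      change_adjusted = std(adjust_covariates(g$change,
                                              cbind(g$covariates,
                                                    baseline = g$baseline)))
    )
    do.call(rbind, lapply(names(outcomes), function(oc) {
      v <- outcomes[[oc]]
      do.call(rbind, lapply(0:2, function(k) {
        sel <- geno == k
        data.frame(group = label, outcome = oc, genotype = k,
                   mean = if (any(sel)) mean(v[sel]) else NA_real_,
                   sd = if (sum(sel) > 1L) stats::sd(v[sel]) else NA_real_,
                   n = sum(sel), stringsAsFactors = FALSE)
      }))
    }))
  }
  out <- rbind(one_group(controls, "control"), one_group(treated, "treated"))
  rownames(out) <- NULL
  class(out) <- c("genotype_strata", "data.frame")
  out
}
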