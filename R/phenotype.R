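# Drug-response phenotype derivation: absolute and log-relative differences,
# covariate residualization, inverse-normal transformation, unit conversion.

#' Absolute or log-relative response from baseline and post values
#'
#' @param baseline,post aligned numeric vectors.
#' @param mode `"absolute"` (post - baseline) or `"log_relative"`
#'   (log(post) - log(baseline), natural logarithm).
#' @return numeric vector; under `log_relative`, rows with a non-positive
#'   baseline or post value are `NA` with a `"dropped"` attribute giving
#'   their indices.
#' @export
response_value <- function(baseline, post, mode = c("absolute", "log_relative")) {
  mode <- match.arg(mode)
  if (mode == "absolute") return(post - baseline)
  bad <- which(!(baseline > 0 & post > 0))
  out <- rep(NA_real_, length(baseline))
  ok <- setdiff(seq_along(out), bad)
  out[ok] <- log(post[ok]) - log(baseline[ok])
  if (length(bad) > 0L) attr(out, "dropped") <- bad
  out
}

#' Build the covariate matrix for association analyses
#'
#' Sex, age at treatment start, time from start to the post-treatment
#' measure, drug-type indicators, dose (where available for every retained
#' row), add-on flags, and `k` generated confounder components standing in
#' for genotype principal components (no population structure is simulated).
#'
#' @param cohort a cohort data.frame from [qc_cascade()].
#' @param k_confounders number of generated confounder columns.
#' @param seed seed for the confounder draws.
#' @return numeric matrix, rows aligned with `cohort`.
#' @export
covariate_matrix <- function(cohort, k_confounders = 4L, seed = 1L) {
  n <- nrow(cohort)
  cols <- list(sex = cohort$sex, age_at_start = cohort$age_at_start,
               time_start_to_post = cohort$time_start_to_post)
  types <- unique(cohort$drug_type)
  if (length(types) > 1L)
    for (ty in types[-1]) cols[[paste0("drug_", ty)]] <- as.numeric(cohort$drug_type == ty)
  if (!is.null(cohort$dose_mg) && !anyNA(cohort$dose_mg))
    cols$dose_mg <- cohort$dose_mg
  if (!is.null(cohort$addon) && any(cohort$addon != ""))
    for (ad in setdiff(unique(unlist(strsplit(cohort$addon, ";"))), ""))
      cols[[paste0("addon_", ad)]] <- as.numeric(grepl(ad, cohort$addon, fixed = TRUE))
  if (k_confounders > 0L) {
    set.seed(derive_seed(seed, 31L))
    pc <- matrix(stats::rnorm(n * k_confounders), n, k_confounders,
                 dimnames = list(NULL, paste0("conf", seq_len(k_confounders))))
    cols <- c(cols, as.data.frame(pc))
  }
  cols <- Filter(Negate(is.null), cols)
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Residualize values on covariates
#'
#' Least-squares residuals of `values` on the covariate columns plus an
#' intercept. Aliased (rank-deficient) columns are dropped with a warning.
#' Residuals are numerically orthogonal to every retained column.
#'
#' @param values numeric vector.
#' @param covariates numeric matrix or `NULL` (intercept only: centering).
#' @return numeric vector of residuals.
#' @export
adjust_covariates <- function(values, covariates = NULL) {
  if (is.null(covariates) || ncol(as.matrix(covariates)) == 0L)
    return(values - mean(values))
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_idx <- qr_x$pivot[seq(qr_x$rank + 1L, ncol(X))]
    warning("dropping aliased covariate column(s): ",
            paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
    qr_x <- qr(X)
  }
  qr.resid(qr_x, values)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles via the Blom offset:
#' `qnorm((rank - offset) / (n + 1 - 2*offset))` with `offset = 3/8`;
#' ties receive the mean of their ranks.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @param offset rank offset, default 3/8 (Blom).
#' @return transformed numeric vector.
#' @export
inverse_normal_transform <- function(values, offset = 3 / 8) {
  if (length(unique(values)) < 2L)
    stop("inverse normal transform needs >= 2 distinct values")
  r <- rank(values, ties.method = "average")
  n <- length(values)
  stats::qnorm((r - offset) / (n + 1 - 2 * offset))
}

#' Convert HbA1c between IFCC (mmol/mol) and NGSP (%) units
#'
#' Uses the NGSP--IFCC master equation NGSP\% = 0.09148 x IFCC + 2.152.
#'
#' @param value numeric vector.
#' @param from,to `"mmol_per_mol"` or `"percent"`.
#' @return converted values.
#' @export
hba1c_convert <- function(value, from, to) {
  units <- c("mmol_per_mol", "percent")
  if (!(from %in% units) || !(to %in% units))
    stop("units must be 'mmol_per_mol' or 'percent'")
  if (from == to) return(value)
  if (from == "mmol_per_mol") 0.09148 * value + 2.152
  else (value - 2.152) / 0.09148
}

#' Derive all response phenotypes for a cohort
#'
#' @param cohort cohort data.frame from [qc_cascade()].
#' @param covariates covariate matrix (default built by [covariate_matrix()]).
#' @return data.frame with absolute and log-relative responses, their
#'   covariate residuals, and inverse-normal-transformed residuals.
#' @export
derive_phenotypes <- function(cohort, covariates = covariate_matrix(cohort)) {
  abs_r <- response_value(cohort$baseline_value, cohort$post_value, "absolute")
  rel_r <- response_value(cohort$baseline_value, cohort$post_value, "log_relative")
  res_abs <- adjust_covariates(abs_r, covariates)
  res_rel <- if (anyNA(rel_r)) rep(NA_real_, length(rel_r)) else
    adjust_covariates(rel_r, covariates)
  data.frame(person_id = cohort$person_id,
             response_abs = abs_r, response_logrel = as.numeric(rel_r),
             residual_abs = res_abs, residual_logrel = res_rel,
             int_abs = inverse_normal_transform(res_abs),
             int_logrel = if (anyNA(res_rel)) NA_real_ else
               inverse_normal_transform(res_rel),
             stringsAsFactors = FALSE)
}
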