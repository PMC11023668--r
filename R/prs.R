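# Polygenic-score analyses: scoring, response association, stratification,
# variance explained.

#' Compute standardized polygenic scores
#'
#' Weighted allele-dosage sum per person, standardized to mean 0 and SD 1 in
#' the analysis sample. If the dosage matrix carries a `counted_allele`
#' attribute, dosages whose counted allele differs from the weight's effect
#' allele are flipped to `2 - g`.
#'
#' @param dosages persons x variants dosage matrix with variant ids as
#'   column names.
#' @param weights data.frame with `variant_id`, `effect_allele`, `weight`.
#' @return standardized numeric score vector.
#' @export
compute_prs <- function(dosages, weights) {
  missing <- setdiff(weights$variant_id, colnames(dosages))
  if (length(missing) > 0L)
    stop("weight variants absent from the dosage panel: ",
         paste(missing, collapse = ", "))
  G <- dosages[, weights$variant_id, drop = FALSE]
  counted <- attr(dosages, "counted_allele")
  if (!is.null(counted)) {
    flip <- counted[weights$variant_id] != weights$effect_allele
    flip[is.na(flip)] <- FALSE
    if (any(flip)) G[, flip] <- 2 - G[, flip]
  }
  raw <- drop(G %*% weights$weight)
  if (stats::sd(raw) == 0) stop("polygenic score has zero variance")
  (raw - mean(raw)) / stats::sd(raw)
}

#' Perturb truth weights to emulate a noisily estimated score
#'
#' Adds independent normal noise to each weight, standing in for the
#' estimation error of externally derived scores.
#'
#' @param weights a weight table (see [compute_prs()]).
#' @param sd perturbation standard deviation.
#' @param seed integer seed.
#' @return the weight table with perturbed weights.
#' @export
perturb_weights <- function(weights, sd = 0.1, seed = 1L) {
  set.seed(derive_seed(seed, 81L))
  weights$weight <- weights$weight + stats::rnorm(nrow(weights), 0, sd)
  weights
}

#' Association between a polygenic score and a drug-response phenotype
#'
#' Least-squares coefficient of the standardized score (effect per 1 SD),
#' optionally with the baseline level appended to the covariates (the biased
#' variant).
#'
#' @param response numeric response vector.
#' @param prs standardized score.
#' @param covariates optional covariate matrix.
#' @param baseline baseline levels; required when `adjust_baseline = TRUE`.
#' @param adjust_baseline add the baseline level to the covariates.
#' @return one-row data.frame: `beta, se, p, n`.
#' @export
prs_response_association <- function(response, prs, covariates = NULL,
                                     baseline = NULL,
                                     adjust_baseline = FALSE) {
  fit <- variant_association(response, prs, covariates = covariates,
                             baseline = baseline,
                             model = if (adjust_baseline) "baseline_adjusted"
                             else "unadjusted",
                             variant_id = "PRS")
  fit[, c("beta", "se", "p", "n")]
}

#' Residualize baseline levels on a polygenic score
#'
#' The residual baseline more closely reflects the environmental component
#' of the starting level.
#'
#' @param baseline,prs aligned numeric vectors.
#' @return residuals of baseline on the score plus an intercept.
#' @export
baseline_adjusted_for_prs <- function(baseline, prs) {
  adjust_covariates(baseline, cbind(prs = prs))
}

# quantile bin index with boundary values assigned to the lower bin
quantile_bin <- function(x, q) {
  br <- stats::quantile(x, probs = seq(0, 1, length.out = q + 1), type = 7)
  br[1] <- -Inf; br[length(br)] <- Inf
  findInterval(x, br, left.open = TRUE, rightmost.closed = TRUE) |>
    pmin(q) |> pmax(1L)
}

#' Stratified mean response by adjusted baseline and score quantiles
#'
#' Cells are PRS-adjusted-baseline quantile x score quintile, optionally
#' further split by one variant's rounded genotype (cells below
#' `min_cell` are reported with `NA` means).
#'
#' @param response_abs,response_rel absolute and relative response vectors.
#' @param baseline baseline levels.
#' @param prs standardized score.
#' @param q_baseline,q_prs numbers of quantile bins (>= 2).
#' @param genotype optional dosage vector of one variant.
#' @param min_cell minimum cell size for reporting a mean.
#' @return data.frame of class `prs_strata`: one row per cell with mean
#'   absolute and relative response and `n`.
#' @export
stratification_table <- function(response_abs, response_rel, baseline, prs,
                                 q_baseline = 3L, q_prs = 5L, genotype = NULL,
                                 min_cell = 1L) {
  stopifnot(q_baseline >= 2L, q_prs >= 2L)
  adj_base <- baseline_adjusted_for_prs(baseline, prs)
  bb <- quantile_bin(adj_base, q_baseline)
  pb <- quantile_bin(prs, q_prs)
  gb <- if (is.null(genotype)) rep(0L, length(prs)) else round(genotype)
  cells <- expand.grid(baseline_bin = seq_len(q_baseline),
                       prs_bin = seq_len(q_prs),
                       genotype = sort(unique(gb)))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- bb == cells$baseline_bin[i] & pb == cells$prs_bin[i] &
      gb == cells$genotype[i]
    n <- sum(sel)
    data.frame(cells[i, , drop = FALSE],
               mean_abs = if (n >= min_cell) mean(response_abs[sel]) else NA_real_,
               mean_rel = if (n >= min_cell) mean(response_rel[sel]) else NA_real_,
               n = n)
  })
  out <- do.call(rbind, rows)
  if (is.null(genotype)) out$genotype <- NULL
  rownames(out) <- NULL
  class(out) <- c("prs_strata", "data.frame")
  out
}

#' In-sample variance explained by nested predictor blocks
#'
#' @param response numeric response vector.
#' @param blocks named list of predictor matrices/vectors; model `k` uses
#'   blocks `1..k` (plus an intercept).
#' @return data.frame with cumulative model labels and in-sample R squared.
#' @export
variance_explained <- function(response, blocks) {
  stopifnot(length(blocks) >= 1L)
  tss <- sum((response - mean(response))^2)
  X <- matrix(1, length(response), 1)
  out <- lapply(seq_along(blocks), function(k) {
    X <<- cbind(X, as.matrix(blocks[[k]]))
    rss <- sum(qr.resid(qr(X), response)^2)
    data.frame(model = paste(names(blocks)[seq_len(k)], collapse = " + "),
               r_squared = 1 - rss / tss, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
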