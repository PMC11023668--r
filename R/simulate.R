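# Synthetic longitudinal-EHR generator.
#
# Biomarker level of person i at time t follows
#   Y_t = intercept + sum_v beta0_v g_v + betaE*E + gammaE*Gc*E
#         + D_t*(betaD + sum_v gammaD_v g_v) + s_sex*sex + s_age*age + S + eps_t
# where E is a persistent per-person environment draw, eps_t i.i.d. occasion
# noise, D_t the drug indicator (1 from the first prescription on), S an
# optional polygenic background, and Gc the centered total dosage used for
# gene-environment interaction. With scale = "log" the linear predictor is
# exponentiated, giving multiplicative (relative) drug action.

derive_seed <- function(seed, stage) {
  # independent substream per stochastic stage; stays below 2^31
  m <- 2147483629
  as.integer((((as.double(seed) %% m) * 48271) %% m + stage) %% m)
}

#' Variant panel specification
#'
#' @param variant_id character ids.
#' @param maf minor allele frequencies in (0, 0.5].
#' @param beta0 baseline genetic effect per effect allele.
#' @param gammaD pharmacogenetic effect per effect allele.
#' @return data.frame of class `variant_panel`.
#' @export
variant_panel <- function(variant_id, maf, beta0 = 0, gammaD = 0) {
  k <- length(variant_id)
  vp <- data.frame(variant_id = as.character(variant_id),
                   maf = as.numeric(maf),
                   beta0 = rep_len(as.numeric(beta0), k),
                   gammaD = rep_len(as.numeric(gammaD), k),
                   stringsAsFactors = FALSE)
  if (any(vp$maf <= 0 | vp$maf > 0.5)) stop("maf must lie in (0, 0.5]")
  if (any(!is.finite(vp$beta0)) || any(!is.finite(vp$gammaD)))
    stop("variant effects must be finite")
  class(vp) <- c("variant_panel", "data.frame")
  vp
}

#' Generative model parameters
#'
#' @param variants a [variant_panel()].
#' @param intercept population mean biomarker (natural or log units per `scale`).
#' @param scale `"natural"` for additive or `"log"` for multiplicative drug
#'   action on the biomarker.
#' @param betaD mean drug effect; `betaE` environment effect; `gammaE`
#'   gene-environment interaction effect.
#' @param var_env_persistent variance of the per-person environment component
#'   shared across all of a person's measures.
#' @param var_env_occasion variance of the occasion-specific noise.
#' @param prs_arch optional `list(var = ...)`: variance of a latent polygenic
#'   background added to the baseline level (for PRS studies).
#' @param sex_effect,age_effect linear nuisance effects (age in decades from
#'   60 years at the study epoch), so covariate adjustment is non-trivial.
#' @return list of class `generative_params`.
#' @export
generative_params <- function(variants = variant_panel("v1", maf = 0.3),
                              intercept = 4, scale = c("natural", "log"),
                              betaD = -1, betaE = 1, gammaE = 0,
                              var_env_persistent = 0.25,
                              var_env_occasion = 0.25,
                              prs_arch = NULL,
                              sex_effect = 0, age_effect = 0) {
  scale <- match.arg(scale)
  if (var_env_persistent < 0 || var_env_occasion < 0)
    stop("variances must be >= 0")
  if (!is.null(prs_arch) && (is.null(prs_arch$var) || prs_arch$var < 0))
    stop("prs_arch must be a list with a non-negative 'var'")
  structure(list(variants = variants, intercept = intercept, scale = scale,
                 betaD = betaD, betaE = betaE, gammaE = gammaE,
                 var_env_persistent = var_env_persistent,
                 var_env_occasion = var_env_occasion,
                 prs_arch = prs_arch,
                 sex_effect = sex_effect, age_effect = age_effect),
            class = "generative_params")
}

#' Prescription-stream behaviour
#'
#' Controls how realistically messy the generated prescription streams are:
#' refill regularity, same-class co-medication, allowed add-on therapy,
#' fixed-dose combination products, and drug/dose switches -- the behaviours
#' the QC cascade is designed to filter.
#'
#' @param mean_interval_days mean refill interval (days).
#' @param regularity probability each scheduled refill is realized, in \[0,1\].
#' @param p_same_class_comed probability of another same-class drug within a
#'   year of treatment start.
#' @param p_addon probability of an allowed add-on drug present both pre- and
#'   post-start (requires `addon_code`).
#' @param p_combo probability the prescribed product is a combination.
#' @param p_switch probability of a drug type or dose change after start.
#' @param addon_code code of the allowed add-on drug, or `NULL`.
#' @return list of class `rx_behavior`.
#' @export
rx_behavior <- function(mean_interval_days = 61, regularity = 0.9,
                        p_same_class_comed = 0.05, p_addon = 0,
                        p_combo = 0.02, p_switch = 0.05, addon_code = NULL) {
  p <- c(regularity, p_same_class_comed, p_addon, p_combo, p_switch)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  if (mean_interval_days <= 0) stop("mean_interval_days must be > 0")
  structure(list(mean_interval_days = mean_interval_days,
                 regularity = regularity,
                 p_same_class_comed = p_same_class_comed,
                 p_addon = p_addon, p_combo = p_combo, p_switch = p_switch,
                 addon_code = addon_code),
            class = "rx_behavior")
}

#' Visit schedule for measurement and treatment-start timing
#'
#' @param rate_pre,rate_post expected measures per year before/after start.
#' @param start_window integer range the treatment start date is drawn from.
#' @param pre_window_days,post_window_days spans sampled around start.
#' @param control_spacing allowed spacing (days) between a control person's
#'   first and second measure.
#' @return list of class `visit_schedule`.
#' @export
visit_schedule <- function(rate_pre = 3, rate_post = 3,
                           start_window = c(900L, 1200L),
                           pre_window_days = 365L, post_window_days = 730L,
                           control_spacing = c(183L, 1095L)) {
  if (rate_pre < 0 || rate_post < 0) stop("rates must be >= 0")
  structure(list(rate_pre = rate_pre, rate_post = rate_post,
                 start_window = as.integer(start_window),
                 pre_window_days = as.integer(pre_window_days),
                 post_window_days = as.integer(post_window_days),
                 control_spacing = as.integer(control_spacing)),
            class = "visit_schedule")
}

#' Simulate a population of genotypes and person-level states
#'
#' Genotype dosages are drawn binomial(2, maf) per variant; each person gets
#' a sex, an age offset, a persistent environment draw and (if configured) a
#' latent polygenic background.
#'
#' @param n number of persons.
#' @param params a [generative_params()].
#' @param seed integer master seed.
#' @param id_prefix prefix for person ids.
#' @return list with `persons` (data.frame) and `dosages` (n x V matrix).
#' @export
simulate_population <- function(n, params, seed, id_prefix = "P") {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, 1L))
  vp <- params$variants
  dos <- vapply(vp$maf, function(m) stats::rbinom(n, 2L, m), numeric(n))
  dos <- matrix(dos, nrow = n, dimnames = list(NULL, vp$variant_id))
  prs_latent <- if (!is.null(params$prs_arch) && params$prs_arch$var > 0)
    stats::rnorm(n, 0, sqrt(params$prs_arch$var)) else numeric(n)
  persons <- data.frame(
    person_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    sex = stats::rbinom(n, 1L, 0.5),
    age_decades = stats::runif(n, -1.5, 1.5),  # decades from 60y at epoch
    env_persistent = stats::rnorm(n, 0, sqrt(params$var_env_persistent)),
    prs_latent = prs_latent,
    stringsAsFactors = FALSE
  )
  rownames(dos) <- persons$person_id
  list(persons = persons, dosages = dos)
}

# Noise-free linear predictor of the model; `dosages` is n x V aligned with
# the rows of the other vectors.
trajectory_mean <- function(params, dosages, env, drug, sex = 0, age = 0,
                            prs_latent = 0) {
  vp <- params$variants
  g0 <- drop(dosages %*% vp$beta0)
  gD <- drop(dosages %*% vp$gammaD)
  gc <- rowSums(dosages) - sum(2 * vp$maf)
  params$intercept + g0 + params$betaE * env + params$gammaE * gc * env +
    drug * (params$betaD + gD) +
    params$sex_effect * sex + params$age_effect * age + prs_latent
}

#' Simulate one person's biomarker trajectory
#'
#' Evaluates the longitudinal model at the given dates with the given drug
#' status and adds occasion noise. The occasion draws are stored in the
#' `"occasion"` attribute so a generated record can be reproduced exactly by
#' re-evaluating the model formula.
#'
#' @param person one-row slice of `persons` from [simulate_population()].
#' @param dosage that person's dosage vector.
#' @param params a [generative_params()].
#' @param dates integer measurement days.
#' @param drug_start day treatment starts (`Inf` for never).
#' @param seed integer seed.
#' @param biomarker,unit codes written into the records.
#' @return measure-record data.frame, one row per date.
#' @export
simulate_trajectory <- function(person, dosage, params, dates, drug_start,
                                seed, biomarker = "LDL", unit = "mmol_per_L") {
  set.seed(derive_seed(seed, 2L))
  k <- length(dates)
  occ <- stats::rnorm(k, 0, sqrt(params$var_env_occasion))
  drug <- as.numeric(dates >= drug_start)
  mu <- trajectory_mean(params, matrix(rep(dosage, each = k), nrow = k),
                        person$env_persistent, drug, person$sex,
                        person$age_decades, person$prs_latent)
  y <- mu + occ
  if (params$scale == "log") y <- exp(y)
  rec <- measure_records(rep(person$person_id, k), dates, biomarker, y, unit)
  attr(rec, "occasion") <- occ
  rec
}

#' Simulate one person's prescription stream
#'
#' Refills are scheduled every `mean_interval_days` from the start date and
#' independently realized with probability `regularity` (the first
#' prescription always occurs). Description text embeds the drug name and
#' dose ("<Drug> <dose>mg tablets"). Co-medication, combination products,
#' allowed add-ons and drug/dose switches are injected per the behaviour
#' probabilities.
#'
#' @param person_id person identifier.
#' @param start_date treatment start day.
#' @param behavior an [rx_behavior()].
#' @param map a [code_map()].
#' @param horizon_days days after start covered by the stream.
#' @param seed integer seed.
#' @param primary primary-medication family (e.g. `"statin"`).
#' @return prescription-record data.frame.
#' @export
simulate_prescriptions <- function(person_id, start_date, behavior, map,
                                   horizon_days = 800L, seed = 1L,
                                   primary = "statin") {
  set.seed(derive_seed(seed, 3L))
  prim <- map[!is.na(map$primary) & map$primary == primary & !map$is_combination, ]
  if (nrow(prim) == 0L) stop("no primary codes for family ", primary)
  cls <- prim$broad_class[1]
  use_combo <- stats::runif(1) < behavior$p_combo
  combo_rows <- map[map$broad_class == cls & map$is_combination &
                      !is.na(map$primary) & map$primary == primary, ]
  code0 <- if (use_combo && nrow(combo_rows) > 0L) combo_rows$code[1] else
    prim$code[sample.int(nrow(prim), 1L)]

  sched <- seq(start_date, start_date + horizon_days,
               by = behavior$mean_interval_days)
  keep <- c(TRUE, stats::runif(length(sched) - 1L) < behavior$regularity)
  dates <- as.integer(sched[keep])
  codes <- rep(code0, length(dates))

  if (stats::runif(1) < behavior$p_switch && length(dates) > 1L) {
    sw_date <- start_date + sample(100:400, 1L)
    after <- dates > sw_date
    if (any(after)) {
      row0 <- map[map$code == code0, ]
      if (stats::runif(1) < 0.5) {  # type change within the family
        alt <- prim[prim$ingredient != row0$ingredient, ]
      } else {                      # dose change, same ingredient
        alt <- prim[prim$ingredient == row0$ingredient &
                      !is.na(prim$dose_mg) & !is.na(row0$dose_mg) &
                      prim$dose_mg != row0$dose_mg, ]
      }
      if (nrow(alt) > 0L)
        codes[after] <- alt$code[sample.int(nrow(alt), 1L)]
    }
  }

  if (stats::runif(1) < behavior$p_same_class_comed) {
    other <- map[map$broad_class == cls & is.na(map$primary) &
                   !map$is_combination, ]
    if (nrow(other) > 0L) {
      dates <- c(dates, start_date + sample(-300:300, 1L))
      codes <- c(codes, other$code[1])
    }
  }

  if (!is.null(behavior$addon_code) && stats::runif(1) < behavior$p_addon) {
    dates <- c(dates, start_date - sample(30:300, 1L),
               start_date + sample(30:300, 1L))
    codes <- c(codes, rep(behavior$addon_code, 2L))
  }

  dates <- pmax(dates, 0L)
  info <- codemap_lookup(map, codes)
  desc <- ifelse(is.na(info$dose_mg),
                 paste(cap_first(info$ingredient), "tablets"),
                 paste0(cap_first(info$ingredient), " ",
                        fmt_num(info$dose_mg), "mg tablets"))
  ord <- order(dates)
  prescription_records(rep(person_id, length(dates))[ord], dates[ord],
                       codes[ord], desc[ord])
}

cap_first <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
fmt_num <- function(x) sub("\\.0+$", "", format(x, trim = TRUE, scientific = FALSE))

# Bulk prescription-stream generator used by simulate_ehr: one draw per
# person for the combo/switch/comed/add-on events, refill thinning done as a
# single Bernoulli matrix. Distributionally identical to calling
# simulate_prescriptions per person, but built from flat vectors.
simulate_rx_bundle <- function(person_ids, starts, behavior, map,
                               horizon_days = 800L, seed = 1L,
                               primary = "statin") {
  set.seed(derive_seed(seed, 23L))
  n <- length(person_ids)
  prim <- map[!is.na(map$primary) & map$primary == primary & !map$is_combination, ]
  if (nrow(prim) == 0L) stop("no primary codes for family ", primary)
  cls <- prim$broad_class[1]
  combo_rows <- map[map$broad_class == cls & map$is_combination &
                      !is.na(map$primary) & map$primary == primary, ]
  other <- map[map$broad_class == cls & is.na(map$primary) &
                 !map$is_combination, ]

  offs <- seq(0L, horizon_days, by = behavior$mean_interval_days)
  nk <- length(offs)
  keep <- matrix(stats::runif(n * nk) < behavior$regularity, n, nk)
  keep[, 1] <- TRUE
  code0 <- prim$code[sample.int(nrow(prim), n, replace = TRUE)]
  if (nrow(combo_rows) > 0L) {
    combo <- stats::runif(n) < behavior$p_combo
    code0[combo] <- combo_rows$code[1]
  }
  codes_m <- matrix(code0[row(keep)], n, nk)

  sw <- stats::runif(n) < behavior$p_switch
  if (any(sw)) {
    sw_date <- starts + sample(100:400, n, replace = TRUE)
    sw_type <- stats::runif(n) < 0.5
    for (i in which(sw)) {
      row0 <- map[map$code == code0[i], ]
      alt <- if (sw_type[i]) prim[prim$ingredient != row0$ingredient, ]
      else prim[prim$ingredient == row0$ingredient & !is.na(prim$dose_mg) &
                  !is.na(row0$dose_mg) & prim$dose_mg != row0$dose_mg, ]
      late <- starts[i] + offs > sw_date[i]
      if (nrow(alt) > 0L && any(late))
        codes_m[i, late] <- alt$code[sample.int(nrow(alt), 1L)]
    }
  }

  sel <- which(keep)
  pid <- person_ids[row(keep)[sel]]
  dts <- (starts[row(keep)[sel]] + offs[col(keep)[sel]])
  cds <- codes_m[sel]

  if (nrow(other) > 0L) {
    com <- which(stats::runif(n) < behavior$p_same_class_comed)
    pid <- c(pid, person_ids[com])
    dts <- c(dts, starts[com] + sample(-300:300, length(com), replace = TRUE))
    cds <- c(cds, rep(other$code[1], length(com)))
  }
  if (!is.null(behavior$addon_code)) {
    ad <- which(stats::runif(n) < behavior$p_addon)
    pid <- c(pid, rep(person_ids[ad], 2L))
    dts <- c(dts, starts[ad] - sample(30:300, length(ad), replace = TRUE),
             starts[ad] + sample(30:300, length(ad), replace = TRUE))
    cds <- c(cds, rep(behavior$addon_code, 2L * length(ad)))
  }

  dts <- pmax(dts, 0L)
  info <- codemap_lookup(map, cds)
  desc <- ifelse(is.na(info$dose_mg),
                 paste(cap_first(info$ingredient), "tablets"),
                 paste0(cap_first(info$ingredient), " ",
                        fmt_num(info$dose_mg), "mg tablets"))
  o <- order(pid, dts)
  prescription_records(pid[o], dts[o], cds[o], desc[o])
}

#' Simulate drug-naive control persons
#'
#' Each control gets two measures whose spacing is drawn uniformly from the
#' allowed control-pair interval, and no prescriptions.
#'
#' @param n number of controls.
#' @param params a [generative_params()].
#' @param schedule a [visit_schedule()].
#' @param seed integer seed.
#' @param biomarker,unit record codes.
#' @return list with `persons`, `dosages`, `measures` and an empty
#'   `prescriptions` table.
#' @export
simulate_controls <- function(n, params, schedule = visit_schedule(), seed = 1L,
                              biomarker = "LDL", unit = "mmol_per_L") {
  pop <- simulate_population(n, params, derive_seed(seed, 11L), id_prefix = "C")
  set.seed(derive_seed(seed, 12L))
  t1 <- sample(0:400, n, replace = TRUE)
  sp <- schedule$control_spacing
  t2 <- t1 + sample(sp[1]:sp[2], n, replace = TRUE)
  occ1 <- stats::rnorm(n, 0, sqrt(params$var_env_occasion))
  occ2 <- stats::rnorm(n, 0, sqrt(params$var_env_occasion))
  mu <- trajectory_mean(params, pop$dosages, pop$persons$env_persistent,
                        drug = 0, sex = pop$persons$sex,
                        age = pop$persons$age_decades,
                        prs_latent = pop$persons$prs_latent)
  y1 <- mu + occ1; y2 <- mu + occ2
  if (params$scale == "log") { y1 <- exp(y1); y2 <- exp(y2) }
  measures <- measure_records(rep(pop$persons$person_id, 2L), c(t1, t2),
                              biomarker, c(y1, y2), unit)
  list(persons = pop$persons, dosages = pop$dosages, measures = measures,
       prescriptions = prescription_records(character(0), integer(0),
                                            character(0)))
}

#' Simulate a full treated EHR bundle
#'
#' Generates a treated population with registration records (so the
#' prior-record QC step is satisfiable), Poisson-sampled pre- and post-start
#' biomarker measures, prescription streams, and the truth needed for
#' parameter-recovery tests.
#'
#' @param n number of treated persons.
#' @param params a [generative_params()].
#' @param behavior an [rx_behavior()].
#' @param schedule a [visit_schedule()].
#' @param seed integer master seed.
#' @param map a [code_map()].
#' @param primary primary-medication family.
#' @param biomarker,unit record codes.
#' @return list with `persons`, `dosages`, `measures`, `prescriptions`,
#'   `start_dates`, and the generating `params`.
#' @export
simulate_ehr <- function(n, params, behavior = rx_behavior(),
                         schedule = visit_schedule(), seed = 1L,
                         map = default_code_map(), primary = "statin",
                         biomarker = "LDL", unit = "mmol_per_L") {
  pop <- simulate_population(n, params, derive_seed(seed, 21L))
  set.seed(derive_seed(seed, 22L))
  starts <- sample(schedule$start_window[1]:schedule$start_window[2], n,
                   replace = TRUE)

  # measurement dates: one early registration record + Poisson visits
  reg_date <- pmax(starts - 750L - sample(0:400, n, replace = TRUE), 0L)
  n_pre <- stats::rpois(n, schedule$rate_pre * schedule$pre_window_days / 365)
  n_post <- stats::rpois(n, schedule$rate_post * schedule$post_window_days / 365)
  idx <- rep(seq_len(n), 1L + n_pre + n_post)
  off <- unlist(lapply(seq_len(n), function(i) {
    c(reg_date[i] - starts[i],
      if (n_pre[i] > 0L) sample((-schedule$pre_window_days):7L, n_pre[i], TRUE),
      if (n_post[i] > 0L) sample(8:schedule$post_window_days, n_post[i], TRUE))
  }))
  dates <- pmax(starts[idx] + off, 0L)
  drug <- as.numeric(dates >= starts[idx])
  occ <- stats::rnorm(length(dates), 0, sqrt(params$var_env_occasion))
  mu <- trajectory_mean(params, pop$dosages[idx, , drop = FALSE],
                        pop$persons$env_persistent[idx], drug,
                        pop$persons$sex[idx], pop$persons$age_decades[idx],
                        pop$persons$prs_latent[idx])
  y <- mu + occ
  if (params$scale == "log") y <- exp(y)
  measures <- measure_records(pop$persons$person_id[idx], dates, biomarker, y,
                              unit)

  prescriptions <- simulate_rx_bundle(pop$persons$person_id, starts, behavior,
                                      map, seed = derive_seed(seed, 23L),
                                      primary = primary)

  list(persons = pop$persons, dosages = pop$dosages, measures = measures,
       prescriptions = prescriptions,
       start_dates = stats::setNames(starts, pop$persons$person_id),
       params = params)
}

#' Write a simulated bundle to TSV files
#'
#' Emits `measures.tsv`, `prescriptions.tsv`, `dosages.tsv` and `truth.tsv`
#' (the generating per-variant parameters) into `dir`.
#'
#' @param bundle output of [simulate_ehr()].
#' @param dir output directory.
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  w(bundle$measures, "measures.tsv")
  w(bundle$prescriptions, "prescriptions.tsv")
  dos <- data.frame(person_id = rownames(bundle$dosages), bundle$dosages,
                    check.names = FALSE)
  w(dos, "dosages.tsv")
  w(bundle$params$variants, "truth.tsv")
  invisible(file.path(dir, c("measures.tsv", "prescriptions.tsv",
                             "dosages.tsv", "truth.tsv")))
}
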