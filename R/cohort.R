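# Cohort emulation: regimen reconstruction and the QC cascade.
#
# Stage order is fixed: co-medication rules, then (i) baseline and
# post-treatment measures available, (ii) a primary care record at least two
# years before treatment start, (iii) a broader-class prescription after the
# post-treatment measure, (iv) no drug change between start and the
# post-treatment measure, (v) regular prescriptions (adherence proxy),
# (vi) minimum baseline level, then the drug-group size rule. Every excluded
# person is counted at their FIRST failing stage only.

QC_STAGES <- c("comed", "baseline_post_measures", "prior_record",
               "rx_after_post", "drug_change", "regularity", "min_baseline",
               "drug_group_size")

#' Scenario configuration for cohort emulation
#'
#' Two packaged scenarios: `"stringent"` (90-day baseline lookback, post
#' window 183--548 days, any treatment change excludes, no add-on therapy)
#' and `"lenient"` (365-day lookback, post window 183--730 days, dose changes
#' tolerated with the start dose kept as covariate, configured add-on
#' therapies allowed as covariates). The baseline window extends 7 days after
#' treatment start, inclusive.
#'
#' @param mode `"stringent"` or `"lenient"`.
#' @param measure_mode `"single"` (closest measure to start for the baseline,
#'   earliest in-window measure for the post value) or `"average"` (mean of
#'   all in-window measures, with their mean date).
#' @param baseline_lookback_days,baseline_after_days baseline window bounds.
#' @param post_min_days,post_max_days post-treatment window bounds.
#' @param comed_exclusion_days same-class co-medication exclusion span around
#'   treatment start.
#' @param prior_record_days required age (days before start) of the oldest
#'   unrelated primary-care record.
#' @param regularity_window_days prescription-regularity window length.
#' @param regularity_threshold minimum fraction of covered windows.
#' @param regularity_mode `"threshold"` or `"min_one"` (at least one refill
#'   strictly between start and the post-treatment measure).
#' @param min_baseline named list of minimum baseline levels per biomarker.
#' @param min_cohort_size cohorts below this size are flagged with a warning.
#' @param min_drug_group_size drug types taken by fewer persons are excluded.
#' @param addon_rules named list mapping a primary family to the ingredients
#'   allowed as add-on therapy (active in lenient mode only).
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("lenient", "stringent"),
                            measure_mode = c("average", "single"),
                            baseline_lookback_days = NULL,
                            baseline_after_days = 7L,
                            post_min_days = 183L,
                            post_max_days = NULL,
                            comed_exclusion_days = 365L,
                            prior_record_days = 730L,
                            regularity_window_days = 61L,
                            regularity_threshold = 0.8,
                            regularity_mode = c("threshold", "min_one"),
                            min_baseline = list(LDL = 2.0),
                            min_cohort_size = 500L,
                            min_drug_group_size = 20L,
                            addon_rules = list(metformin = "gliclazide")) {
  mode <- match.arg(mode)
  measure_mode <- match.arg(measure_mode)
  regularity_mode <- match.arg(regularity_mode)
  if (is.null(baseline_lookback_days))
    baseline_lookback_days <- if (mode == "stringent") 90L else 365L
  if (is.null(post_max_days))
    post_max_days <- if (mode == "stringent") 548L else 730L
  if (post_min_days >= post_max_days) stop("post_min_days must be < post_max_days")
  if (baseline_lookback_days <= 0) stop("baseline_lookback_days must be > 0")
  if (regularity_threshold < 0 || regularity_threshold > 1)
    stop("regularity_threshold must lie in [0, 1]")
  structure(list(mode = mode, measure_mode = measure_mode,
                 baseline_lookback_days = as.integer(baseline_lookback_days),
                 baseline_after_days = as.integer(baseline_after_days),
                 post_min_days = as.integer(post_min_days),
                 post_max_days = as.integer(post_max_days),
                 comed_exclusion_days = as.integer(comed_exclusion_days),
                 prior_record_days = as.integer(prior_record_days),
                 regularity_window_days = as.integer(regularity_window_days),
                 regularity_threshold = regularity_threshold,
                 regularity_mode = regularity_mode,
                 min_baseline = min_baseline,
                 min_cohort_size = as.integer(min_cohort_size),
                 min_drug_group_size = as.integer(min_drug_group_size),
                 addon_rules = if (mode == "lenient") addon_rules else list()),
            class = "scenario_config")
}

#' Annotate prescriptions with code-map fields
#'
#' Tags each record with the broad class, ingredient, combination flag,
#' whether it is the primary medication under analysis, and whether it is
#' another drug of the same class. Unresolvable codes are quarantined.
#'
#' @param records prescription records.
#' @param map a [code_map()].
#' @param primary primary-medication family under analysis.
#' @return list with `records` (annotated) and `rejects`.
#' @export
classify_prescriptions <- function(records, map, primary) {
  info <- codemap_lookup(map, records$code)
  unknown <- is.na(info$broad_class)
  rejects <- cbind(records[unknown, , drop = FALSE],
                   reason = rep("unknown drug code", sum(unknown)))
  records <- records[!unknown, , drop = FALSE]
  info <- info[!unknown, , drop = FALSE]
  prim_class <- map$broad_class[!is.na(map$primary) & map$primary == primary][1]
  records$broad_class <- info$broad_class
  records$ingredient <- info$ingredient
  records$is_combination <- info$is_combination
  records$is_primary <- !is.na(info$primary) & info$primary == primary &
    !info$is_combination
  records$is_same_class_other <- info$broad_class %in% prim_class &
    !records$is_primary
  records$map_dose_mg <- info$dose_mg
  list(records = records, rejects = rejects)
}

#' Extract a dose in mg from free-text drug descriptions
#'
#' The first occurrence of a number immediately followed by an optional space
#' and "mg" (case-insensitive) is taken; otherwise the dose is missing.
#'
#' @param description character vector.
#' @return numeric vector (NA where no dose pattern is found).
#' @export
parse_dose <- function(description) {
  m <- regmatches(description,
                  regexpr("[0-9]+(\\.[0-9]+)?(?= ?mg)", description,
                          perl = TRUE, ignore.case = TRUE))
  out <- rep(NA_real_, length(description))
  out[regexpr("[0-9]+(\\.[0-9]+)?(?= ?mg)", description, perl = TRUE,
              ignore.case = TRUE) > 0] <- as.numeric(m)
  out
}

#' Impute missing start doses by the per-drug-type median
#'
#' @param regimens data.frame of regimens (see [build_regimen()]).
#' @return `regimens` with missing `start_dose` filled in and a
#'   `dose_imputed` flag; drug types with no observed dose at all keep `NA`
#'   and are flagged `dose_unavailable` (excluded from the dose covariate,
#'   not from the cohort).
#' @export
impute_missing_dose <- function(regimens) {
  regimens$dose_imputed <- FALSE
  regimens$dose_unavailable <- FALSE
  for (ty in unique(regimens$drug_type)) {
    i <- regimens$drug_type == ty
    obs <- regimens$start_dose[i]
    if (all(is.na(obs))) {
      regimens$dose_unavailable[i] <- TRUE
    } else if (anyNA(obs)) {
      med <- stats::median(obs, na.rm = TRUE)
      fill <- i & is.na(regimens$start_dose)
      regimens$start_dose[fill] <- med
      regimens$dose_imputed[fill] <- TRUE
    }
  }
  regimens
}

#' Reconstruct one person's medication regimen
#'
#' Treatment start is the earliest primary-medication prescription. Switch
#' events are detected by comparing consecutive primary prescriptions'
#' ingredient and parsed dose. Combination products of the same class always
#' violate the co-medication rule; other same-class drugs within the
#' exclusion span violate it unless they are a configured add-on (lenient
#' mode) present both before and after start, in which case an add-on flag is
#' set instead.
#'
#' @param rx annotated prescriptions of one person
#'   (from [classify_prescriptions()]).
#' @param scenario a [scenario_config()].
#' @param primary primary-medication family.
#' @return one-row list describing the regimen, or `NULL` if the person has
#'   no primary-medication prescription (not a candidate).
#' @export
build_regimen <- function(rx, scenario, primary) {
  regimen_from_vectors(rx$person_id, rx$date, rx$ingredient, rx$is_primary,
                       rx$is_combination, rx$is_same_class_other,
                       rx$broad_class, rx$description, rx$map_dose_mg,
                       scenario, primary)
}

# vector-based core of build_regimen (one person's annotated prescriptions
# as flat columns; avoids per-person data.frame construction in the cascade)
regimen_from_vectors <- function(person_id, date, ingredient, is_primary,
                                 is_combination, is_same_class_other,
                                 broad_class, description, map_dose_mg,
                                 scenario, primary) {
  pi <- which(is_primary)
  if (length(pi) == 0L) return(NULL)
  pi <- pi[order(date[pi])]
  p_date <- date[pi]
  p_ing <- ingredient[pi]
  start <- p_date[1]
  dose <- parse_dose(description[pi])
  dose[is.na(dose)] <- map_dose_mg[pi][is.na(dose)]

  # switch events between consecutive primary prescriptions
  sw_date <- integer(0); sw_kind <- character(0)
  np <- length(pi)
  if (np > 1L) {
    ing_ch <- p_ing[-1] != p_ing[-np]
    dose_ch <- !ing_ch & !is.na(dose[-1]) & !is.na(dose[-np]) &
      dose[-1] != dose[-np]
    sw_date <- c(p_date[-1][ing_ch], p_date[-1][dose_ch])
    sw_kind <- c(rep("type_change", sum(ing_ch)),
                 rep("dose_change", sum(dose_ch)))
  }

  # co-medication rules around treatment start
  comed_violation <- NA_character_
  addon <- character(0)
  near <- abs(date - start) <= scenario$comed_exclusion_days
  if (any(is_combination & is_same_class_other & near)) {
    comed_violation <- "same_class_combination"
  } else {
    oth <- is_same_class_other & !is_combination & near
    allowed <- scenario$addon_rules[[primary]]
    for (ing in unique(ingredient[oth])) {
      dts <- date[ingredient == ing & is_same_class_other]
      if (!is.null(allowed) && ing %in% allowed &&
          any(dts < start) && any(dts > start)) {
        addon <- c(addon, ing)       # consistent pre/post add-on: covariate
      } else {
        comed_violation <- paste0("same_class_comed:", ing)
      }
    }
  }

  list(person_id = person_id[1], start = start,
       drug_type = p_ing[1], start_dose = dose[1],
       switch_dates = sw_date, switch_kinds = sw_kind,
       regularity = NA_real_, addon = addon,
       comed_violation = comed_violation,
       prim_dates = p_date,
       class_dates = date[broad_class == broad_class[pi[1]]])
}

#' Prescription regularity (adherence proxy)
#'
#' Partitions `[start, end)` into consecutive windows of
#' `window_days` days (a trailing partial window counts if at least 30 days
#' long) and returns the fraction of windows containing at least one
#' prescription.
#'
#' @param dates prescription dates of the primary medication.
#' @param start,end interval bounds (days), `end > start`.
#' @param window_days window length, default 61 (two months).
#' @return a fraction in \[0, 1\].
#' @export
regularity <- function(dates, start, end, window_days = 61L) {
  if (end <= start) stop("end must be > start")
  ws <- seq(start, end - 1L, by = window_days)
  we <- pmin(ws + window_days, end)
  keep <- (we - ws) >= window_days | (we - ws) >= 30
  ws <- ws[keep]; we <- we[keep]
  if (length(ws) == 0L) return(0)
  covered <- vapply(seq_along(ws),
                    function(i) any(dates >= ws[i] & dates < we[i]), logical(1))
  mean(covered)
}

#' Select the baseline or post-treatment measure from a window
#'
#' @param dates,values aligned measure dates and values.
#' @param lo,hi window bounds in absolute days.
#' @param start treatment start (for the closest-to-start rule).
#' @param measure_mode `"single"` or `"average"`.
#' @param pick `"closest"` (baseline: minimal |date - start|, ties to the
#'   earlier, pre-treatment measure) or `"earliest"` (post window).
#' @param inclusive_hi whether `hi` itself is inside the window (TRUE for the
#'   baseline's +7-day bound; the post window is half-open).
#' @return list `(value, date, n)` or `NULL` if no in-window measure.
#' @export
select_window_measure <- function(dates, values, lo, hi, start,
                                  measure_mode = c("average", "single"),
                                  pick = c("closest", "earliest"),
                                  inclusive_hi = TRUE) {
  measure_mode <- match.arg(measure_mode)
  pick <- match.arg(pick)
  inw <- dates >= lo & (if (inclusive_hi) dates <= hi else dates < hi)
  if (!any(inw)) return(NULL)
  d <- dates[inw]; v <- values[inw]
  if (measure_mode == "average")
    return(list(value = mean(v), date = mean(d), n = length(v)))
  i <- if (pick == "closest") {
    o <- order(abs(d - start), d)  # tie at equal distance: earlier wins
    o[1]
  } else which.min(d)
  list(value = v[i], date = d[i], n = 1L)
}

#' Apply the QC cascade and emit a drug-response cohort with audit
#'
#' @param measures measure records of the analysed biomarker.
#' @param prescriptions prescription records.
#' @param map a [code_map()].
#' @param scenario a [scenario_config()].
#' @param primary primary-medication family under analysis.
#' @param biomarker biomarker code the response is derived for.
#' @param persons optional data.frame with `person_id`, `sex`, `age_decades`
#'   used to fill cohort covariates.
#' @return list with `cohort` (one row per survivor), `audit` (a `qc_audit`),
#'   `regimens`, and `rejects` from code resolution.
#' @export
qc_cascade <- function(measures, prescriptions, map, scenario,
                       primary = "statin", biomarker = "LDL",
                       persons = NULL) {
  cls <- classify_prescriptions(prescriptions, map, primary)
  rx <- cls$records
  meas <- measures[measures$biomarker == biomarker, , drop = FALSE]

  rx_by <- split(seq_len(nrow(rx)), rx$person_id)
  regs <- Filter(Negate(is.null), lapply(rx_by, function(i)
    regimen_from_vectors(rx$person_id[i], rx$date[i], rx$ingredient[i],
                         rx$is_primary[i], rx$is_combination[i],
                         rx$is_same_class_other[i], rx$broad_class[i],
                         rx$description[i], rx$map_dose_mg[i],
                         scenario, primary)))
  if (length(regs) == 0L)
    return(list(cohort = data.frame(), audit = qc_audit(integer(length(QC_STAGES)), 0L, 0L,
                                                        character(0), scenario),
                regimens = list(), rejects = cls$rejects))

  reg_df <- data.frame(person_id = vapply(regs, `[[`, "", "person_id"),
                       drug_type = vapply(regs, `[[`, "", "drug_type"),
                       start_dose = vapply(regs, `[[`, 0, "start_dose"),
                       stringsAsFactors = FALSE)
  reg_df$start_dose[is.nan(reg_df$start_dose)] <- NA_real_
  reg_df <- impute_missing_dose(reg_df)

  md_by <- split(seq_len(nrow(meas)), meas$person_id)
  nr <- length(regs)
  first_fail <- stats::setNames(rep(NA_character_, nr), reg_df$person_id)
  # accumulator vectors (one slot per candidate; survivors selected at the end)
  acc <- list(baseline_value = rep(NA_real_, nr), baseline_date = rep(NA_real_, nr),
              n_baseline = rep(NA_integer_, nr), post_value = rep(NA_real_, nr),
              post_date = rep(NA_real_, nr), n_post = rep(NA_integer_, nr),
              regularity = rep(NA_real_, nr), addon = rep("", nr))

  for (k in seq_len(nr)) {
    r <- regs[[k]]
    pid <- r$person_id

    if (!is.na(r$comed_violation)) { first_fail[k] <- "comed"; next }

    mi <- md_by[[pid]]
    d <- meas$date[mi]; v <- meas$value[mi]
    base <- select_window_measure(d, v,
                                  lo = r$start - scenario$baseline_lookback_days,
                                  hi = r$start + scenario$baseline_after_days,
                                  start = r$start,
                                  measure_mode = scenario$measure_mode,
                                  pick = "closest", inclusive_hi = TRUE)
    post <- select_window_measure(d, v,
                                  lo = r$start + scenario$post_min_days,
                                  hi = r$start + scenario$post_max_days,
                                  start = r$start,
                                  measure_mode = scenario$measure_mode,
                                  pick = "earliest", inclusive_hi = FALSE)
    if (is.null(base) || is.null(post)) {
      first_fail[k] <- "baseline_post_measures"; next
    }

    # (ii) unrelated primary-care record >= 2 years before start: any measure
    # or any non-primary prescription old enough
    ri <- rx_by[[pid]]
    old_rx <- rx$date[ri][!rx$is_primary[ri]]
    has_prior <- any(d <= r$start - scenario$prior_record_days) ||
      any(old_rx <= r$start - scenario$prior_record_days)
    if (!has_prior) { first_fail[k] <- "prior_record"; next }

    if (!any(r$class_dates > post$date)) {
      first_fail[k] <- "rx_after_post"; next
    }

    in_span <- r$switch_dates > r$start & r$switch_dates <= post$date
    changed <- if (scenario$mode == "stringent") any(in_span)
    else any(in_span & r$switch_kinds == "type_change")
    if (changed) { first_fail[k] <- "drug_change"; next }

    reg_frac <- regularity(r$prim_dates, r$start, post$date,
                           scenario$regularity_window_days)
    regs[[k]]$regularity <- reg_frac
    reg_ok <- if (scenario$regularity_mode == "min_one")
      any(r$prim_dates > r$start & r$prim_dates <= post$date)
    else reg_frac >= scenario$regularity_threshold
    if (!reg_ok) { first_fail[k] <- "regularity"; next }

    minb <- scenario$min_baseline[[biomarker]]
    if (!is.null(minb) && base$value < minb) {
      first_fail[k] <- "min_baseline"; next
    }

    acc$baseline_value[k] <- base$value; acc$baseline_date[k] <- base$date
    acc$n_baseline[k] <- base$n
    acc$post_value[k] <- post$value; acc$post_date[k] <- post$date
    acc$n_post[k] <- post$n
    acc$regularity[k] <- reg_frac
    acc$addon[k] <- if (length(r$addon)) paste(r$addon, collapse = ";") else ""
  }

  surv <- which(is.na(first_fail))
  cohort <- if (length(surv) > 0L) data.frame(
    person_id = reg_df$person_id[surv],
    baseline_value = acc$baseline_value[surv],
    baseline_date = acc$baseline_date[surv],
    n_baseline_measures = acc$n_baseline[surv],
    post_value = acc$post_value[surv],
    post_date = acc$post_date[surv],
    n_post_measures = acc$n_post[surv],
    time_start_to_post = acc$post_date[surv] -
      vapply(regs[surv], `[[`, 0, "start"),
    start_date = vapply(regs[surv], `[[`, 0, "start"),
    drug_type = reg_df$drug_type[surv],
    dose_mg = reg_df$start_dose[surv],
    dose_imputed = reg_df$dose_imputed[surv] | reg_df$dose_unavailable[surv],
    addon = acc$addon[surv],
    regularity = acc$regularity[surv],
    stringsAsFactors = FALSE
  ) else data.frame()

  # drug-group size rule on survivors
  if (nrow(cohort) > 0L) {
    sizes <- table(cohort$drug_type)
    small <- names(sizes)[sizes < scenario$min_drug_group_size]
    if (length(small) > 0L) {
      drop <- cohort$drug_type %in% small
      first_fail[match(cohort$person_id[drop], reg_df$person_id)] <-
        "drug_group_size"
      cohort <- cohort[!drop, , drop = FALSE]
    }
  }

  if (!is.null(persons) && nrow(cohort) > 0L) {
    i <- match(cohort$person_id, persons$person_id)
    cohort$sex <- persons$sex[i]
    cohort$age_at_start <- persons$age_decades[i] + cohort$start_date / 3652.5
  }

  removed <- vapply(QC_STAGES, function(s) sum(first_fail == s, na.rm = TRUE),
                    integer(1))
  audit <- qc_audit(removed, input_n = length(regs), survivors = nrow(cohort),
                    first_fail = first_fail, scenario = scenario)
  if (nrow(cohort) > 0L && nrow(cohort) < scenario$min_cohort_size) {
    attr(cohort, "below_min_cohort_size") <- TRUE
    warning(sprintf("cohort size %d below minimum %d", nrow(cohort),
                    scenario$min_cohort_size), call. = FALSE)
  }
  rownames(cohort) <- NULL
  list(cohort = cohort, audit = audit, regimens = regs, rejects = cls$rejects)
}

qc_audit <- function(removed, input_n, survivors, first_fail, scenario) {
  structure(list(stages = QC_STAGES, removed = as.integer(removed),
                 input_n = as.integer(input_n),
                 survivors = as.integer(survivors),
                 first_fail = first_fail,
                 mode = scenario$mode, measure_mode = scenario$measure_mode),
            class = "qc_audit")
}

#' @export
print.qc_audit <- function(x, ...) {
  cat(sprintf("QC audit (%s filtering, %s measures)\n", x$mode, x$measure_mode))
  cat(sprintf("  candidates: %d\n", x$input_n))
  for (i in seq_along(x$stages))
    cat(sprintf("  removed at %-22s %6d\n", x$stages[i], x$removed[i]))
  cat(sprintf("  survivors:  %d\n", x$survivors))
  invisible(x)
}

#' Pair first and second measures of drug-naive persons
#'
#' Walks each person's measures in date order and keeps the earliest pair
#' whose spacing lies within the allowed interval.
#'
#' @param measures measure records of drug-naive persons.
#' @param biomarker biomarker code.
#' @param spacing allowed spacing `c(min, max)` in days (inclusive).
#' @return data.frame with one row per retained person: first/second value,
#'   dates and spacing.
#' @export
control_pairs <- function(measures, biomarker = "LDL",
                          spacing = c(183L, 1095L)) {
  meas <- measures[measures$biomarker == biomarker, , drop = FALSE]
  by <- split(seq_len(nrow(meas)), meas$person_id)
  rows <- lapply(by, function(mi) {
    d <- meas$date[mi]; v <- meas$value[mi]
    o <- order(d); d <- d[o]; v <- v[o]
    for (i in seq_along(d)) {
      j <- which(d - d[i] >= spacing[1] & d - d[i] <= spacing[2])
      j <- j[j > i]
      if (length(j) > 0L) {
        j <- j[1]
        return(data.frame(person_id = meas$person_id[mi[1]],
                          first_value = v[i], first_date = d[i],
                          second_value = v[j], second_date = d[j],
                          spacing = d[j] - d[i], stringsAsFactors = FALSE))
      }
    }
    NULL
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}
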