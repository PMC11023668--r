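#' Drug code maps
#'
#' A code map resolves opaque prescription codes to the fields the cohort
#' emulation needs: the broad medication class (e.g. lipid-regulating), the
#' primary-medication family the code belongs to (e.g. "statin"; `NA` for
#' drugs that are never a primary medication, such as ezetimibe), the active
#' ingredient, the tablet strength in mg where the code implies one, and a
#' flag marking fixed-dose combination products of two same-class agents.
#'
#' This is a deliberately small stand-in for real drug vocabularies
#' (BNF/Read/RxNorm); only the structure matters to the pipeline.
#'
#' @param code character vector of unique drug codes.
#' @param broad_class broad medication class per code.
#' @param primary primary-medication family per code, or `NA`.
#' @param ingredient active ingredient(s) per code.
#' @param dose_mg tablet strength in mg, or `NA`.
#' @param is_combination logical; `TRUE` for fixed-dose same-class combinations.
#' @return A `data.frame` of class `code_map`.
#' @export
code_map <- function(code, broad_class, primary, ingredient, dose_mg, is_combination) {
  stopifnot(!anyDuplicated(code))
  cm <- data.frame(
    code = as.character(code),
    broad_class = as.character(broad_class),
    primary = as.character(primary),
    ingredient = as.character(ingredient),
    dose_mg = as.numeric(dose_mg),
    is_combination = as.logical(is_combination),
    stringsAsFactors = FALSE
  )
  # a primary family must live inside a single broad class
  fam <- cm[!is.na(cm$primary), ]
  if (nrow(fam) > 0L) {
    per_fam <- tapply(fam$broad_class, fam$primary, function(x) length(unique(x)))
    if (any(per_fam > 1L))
      stop("each primary-medication family must belong to exactly one broad class")
  }
  class(cm) <- c("code_map", "data.frame")
  cm
}

#' Built-in toy code map
#'
#' Covers three broad classes (lipid-regulating, antidiabetic,
#' antihypertensive) with the drug families the synthetic scenarios use:
#' statins (with an ezetimibe co-medication and a statin+ezetimibe
#' combination product), metformin (with sulfonylureas as a possible add-on
#' and a fixed-dose combination), and a few antihypertensive families.
#'
#' @return A [code_map()].
#' @export
default_code_map <- function() {
  rows <- list(
    # code,          class,        primary,        ingredient,                 dose, combo
    c("SIMVA10",  "lipid",  "statin",       "simvastatin",  "10", "FALSE"),
    c("SIMVA20",  "lipid",  "statin",       "simvastatin",  "20", "FALSE"),
    c("SIMVA40",  "lipid",  "statin",       "simvastatin",  "40", "FALSE"),
    c("SIMVA80",  "lipid",  "statin",       "simvastatin",  "80", "FALSE"),
    c("ATORV10",  "lipid",  "statin",       "atorvastatin", "10", "FALSE"),
    c("ATORV20",  "lipid",  "statin",       "atorvastatin", "20", "FALSE"),
    c("ATORV40",  "lipid",  "statin",       "atorvastatin", "40", "FALSE"),
    c("ROSUV5",   "lipid",  "statin",       "rosuvastatin", "5",  "FALSE"),
    c("ROSUV10",  "lipid",  "statin",       "rosuvastatin", "10", "FALSE"),
    c("EZET10",   "lipid",  NA,             "ezetimibe",    "10", "FALSE"),
    c("FIBR200",  "lipid",  NA,             "fenofibrate",  "200", "FALSE"),
    c("SIMVEZE",  "lipid",  "statin",       "simvastatin+ezetimibe", NA, "TRUE"),
    c("METF500",  "antidiabetic", "metformin",    "metformin",   "500", "FALSE"),
    c("METF850",  "antidiabetic", "metformin",    "metformin",   "850", "FALSE"),
    c("METF1000", "antidiabetic", "metformin",    "metformin",   "1000", "FALSE"),
    c("GLIC80",   "antidiabetic", "sulfonylurea", "gliclazide",  "80",  "FALSE"),
    c("METFGLI",  "antidiabetic", "metformin",    "metformin+glibenclamide", NA, "TRUE"),
    c("INSUL",    "antidiabetic", NA,             "insulin",     NA,    "FALSE"),
    c("AMLO5",    "antihypertensive", "ccb",          "amlodipine",  "5",  "FALSE"),
    c("AMLO10",   "antihypertensive", "ccb",          "amlodipine",  "10", "FALSE"),
    c("LISIN10",  "antihypertensive", "acei",         "lisinopril",  "10", "FALSE"),
    c("LISIN20",  "antihypertensive", "acei",         "lisinopril",  "20", "FALSE"),
    c("BENDR2",   "antihypertensive", "thiazide",     "bendroflumethiazide", "2.5", "FALSE"),
    c("ATEN50",   "antihypertensive", "beta_blocker", "atenolol",    "50", "FALSE")
  )
  m <- do.call(rbind, rows)
  code_map(
    code = m[, 1], broad_class = m[, 2], primary = m[, 3],
    ingredient = m[, 4], dose_mg = suppressWarnings(as.numeric(m[, 5])),
    is_combination = as.logical(m[, 6])
  )
}

#' Look up code-map rows for a vector of codes
#'
#' @param map a [code_map()].
#' @param codes character vector; codes absent from the map yield `NA` fields.
#' @return data.frame with one row per element of `codes`.
#' @keywords internal
codemap_lookup <- function(map, codes) {
  idx <- match(codes, map$code)
  out <- map[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
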