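#' @keywords internal
"_PACKAGE"

# Closed set of biomarkers and their allowed unit codes. Dates are integer
# days from an arbitrary study epoch; windows are half-open [a, b) except the
# baseline upper bound (start + 7 days), which is inclusive.
BIOMARKER_UNITS <- list(
  LDL   = c("mmol_per_L", "mg_per_dL"),
  HDL   = c("mmol_per_L", "mg_per_dL"),
  TC    = c("mmol_per_L", "mg_per_dL"),
  HBA1C = c("mmol_per_mol", "percent"),
  SBP   = c("mmHg"),
  HR    = c("bpm")
)

#' Validated longitudinal measure records
#'
#' @param person_id,date,biomarker,value,unit,source column vectors; `date` is
#'   integer days from the study epoch, `source` is `"ehr"` or `"assessment"`.
#' @return data.frame with the canonical measure-record columns.
#' @export
measure_records <- function(person_id, date, biomarker, value, unit,
                            source = "ehr") {
  df <- data.frame(
    person_id = as.character(person_id),
    date = as.integer(date),
    biomarker = as.character(biomarker),
    value = as.numeric(value),
    unit = as.character(unit),
    source = rep_len(as.character(source), length(person_id)),
    stringsAsFactors = FALSE
  )
  bad <- validate_measures(df)
  if (any(bad != "")) stop("invalid measure record(s): ", bad[bad != ""][1])
  df
}

validate_measures <- function(df) {
  reason <- character(nrow(df))
  reason[!is.finite(df$value)] <- "non-finite value"
  reason[is.na(df$date) | df$date < 0L] <- "negative or missing date"
  known <- df$biomarker %in% names(BIOMARKER_UNITS)
  reason[!known] <- "unknown biomarker"
  ok_unit <- mapply(function(b, u) b %in% names(BIOMARKER_UNITS) &&
                      !is.na(u) && u %in% BIOMARKER_UNITS[[b]],
                    df$biomarker, df$unit, USE.NAMES = FALSE)
  reason[known & !ok_unit] <- "unit not allowed for biomarker"
  reason[is.na(df$unit) | df$unit == ""] <- "missing unit"
  reason
}

#' Validated prescription records
#'
#' @param person_id,date,code,description,quantity column vectors.
#' @return data.frame with the canonical prescription-record columns.
#' @export
prescription_records <- function(person_id, date, code, description = "",
                                 quantity = NA_integer_) {
  df <- data.frame(
    person_id = as.character(person_id),
    date = as.integer(date),
    code = as.character(code),
    description = rep_len(as.character(description), length(person_id)),
    quantity = rep_len(as.integer(quantity), length(person_id)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$date) | df$date < 0L)) stop("prescription dates must be >= 0")
  df
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("%s (%s): missing column(s) %s",
                 what, path, paste(missing, collapse = ", ")))
  df
}

#' Read a measures table
#'
#' Tab-separated with header `person_id date biomarker value unit source`.
#' Rows with unknown biomarkers, disallowed units or non-finite values are not
#' silently dropped: they are returned in a rejects table with a reason.
#'
#' @param path file path.
#' @return list with elements `records` and `rejects`.
#' @export
read_measures <- function(path) {
  df <- read_tsv_checked(path, c("person_id", "date", "biomarker", "value", "unit"),
                         "measures table")
  if (is.null(df$source)) df$source <- "ehr"
  n <- nrow(df)
  if (n == 0L) {
    return(list(records = measure_records(character(0), integer(0), character(0),
                                          numeric(0), character(0), character(0)),
                rejects = data.frame()))
  }
  date_num <- suppressWarnings(as.numeric(df$date))
  if (anyNA(date_num)) {
    i <- which(is.na(date_num))[1]
    stop(sprintf("malformed row in %s: line %d, column 'date'", path, i + 1L))
  }
  val_num <- suppressWarnings(as.numeric(df$value))
  df$date <- as.integer(date_num)
  df$value <- val_num
  reason <- validate_measures(df)
  rejects <- cbind(df[reason != "", , drop = FALSE],
                   reason = reason[reason != ""])
  list(records = df[reason == "", , drop = FALSE], rejects = rejects)
}

#' Read a prescriptions table
#'
#' Tab-separated with header `person_id date code description quantity`.
#' Codes not resolvable by `map` are quarantined into the rejects table.
#'
#' @param path file path.
#' @param map optional [code_map()]; when given, unknown codes are rejected.
#' @return list with elements `records` and `rejects`.
#' @export
read_prescriptions <- function(path, map = NULL) {
  df <- read_tsv_checked(path, c("person_id", "date", "code"), "prescriptions table")
  if (is.null(df$description)) df$description <- ""
  if (is.null(df$quantity)) df$quantity <- NA_integer_
  if (nrow(df) > 0L) {
    date_num <- suppressWarnings(as.numeric(df$date))
    if (anyNA(date_num)) {
      i <- which(is.na(date_num))[1]
      stop(sprintf("malformed row in %s: line %d, column 'date'", path, i + 1L))
    }
    df$date <- as.integer(date_num)
  }
  rejects <- df[0, , drop = FALSE]
  if (!is.null(map) && nrow(df) > 0L) {
    known <- df$code %in% map$code
    rejects <- cbind(df[!known, , drop = FALSE],
                     reason = rep("unknown drug code", sum(!known)))
    df <- df[known, , drop = FALSE]
  }
  list(records = df, rejects = rejects)
}

#' Read a plain dosage matrix
#'
#' Tab-separated, first column `person_id`, remaining columns one variant
#' each with allele dosages in \[0, 2\]. Variants with zero variance are kept
#' but flagged monomorphic (attribute `monomorphic`).
#'
#' @param path file path.
#' @return numeric matrix (persons x variants) with `person_id` rownames.
#' @export
read_dosages <- function(path) {
  df <- read_tsv_checked(path, "person_id", "dosage matrix")
  ids <- as.character(df$person_id)
  m <- as.matrix(df[, setdiff(names(df), "person_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0 | m > 2))
    stop("dosages must be finite and within [0, 2]: ", path)
  rownames(m) <- ids
  attr(m, "monomorphic") <- colnames(m)[apply(m, 2, stats::var) == 0]
  m
}

#' Read allele dosages from a VCF file
#'
#' Extracts dosages from the `DS` FORMAT field if present, otherwise counts
#' alternate alleles in `GT`. Requires the `vcfR` package.
#'
#' @param path VCF file path (uncompressed or bgzipped).
#' @return numeric matrix (persons x variants), as [read_dosages()].
#' @export
read_dosages_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF dosages requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    ds <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0L)
    })
  }
  m <- t(ds)
  ids <- vcfR::getID(v)
  colnames(m) <- ifelse(is.na(ids) | ids == ".",
                        paste0("var", seq_len(ncol(m))), ids)
  storage.mode(m) <- "double"
  attr(m, "monomorphic") <- colnames(m)[apply(m, 2, stats::var) == 0]
  m
}

#' Read a PRS weight table
#'
#' Tab-separated with header `variant_id effect_allele weight`.
#'
#' @param path file path.
#' @return data.frame with unique `variant_id` and finite weights.
#' @export
read_weights <- function(path) {
  df <- read_tsv_checked(path, c("variant_id", "effect_allele", "weight"),
                         "weights table")
  df$weight <- as.numeric(df$weight)
  if (anyDuplicated(df$variant_id)) stop("duplicate variant_id in ", path)
  if (nrow(df) > 0L && any(!is.finite(df$weight)))
    stop("non-finite weight in ", path)
  df
}

#' Read every pipeline input in one call
#'
#' @param paths named list with any of `measures`, `prescriptions`, `dosages`
#'   (TSV) or `vcf`, and `weights`.
#' @param map optional [code_map()] for prescription-code screening.
#' @return list with `measures`, `prescriptions`, `dosages`, `weights`,
#'   `rejects`.
#' @export
read_tables <- function(paths, map = NULL) {
  out <- list(measures = NULL, prescriptions = NULL, dosages = NULL,
              weights = NULL, rejects = list())
  if (!is.null(paths$measures)) {
    m <- read_measures(paths$measures)
    out$measures <- m$records
    out$rejects$measures <- m$rejects
  }
  if (!is.null(paths$prescriptions)) {
    p <- read_prescriptions(paths$prescriptions, map)
    out$prescriptions <- p$records
    out$rejects$prescriptions <- p$rejects
  }
  if (!is.null(paths$dosages)) out$dosages <- read_dosages(paths$dosages)
  if (!is.null(paths$vcf)) out$dosages <- read_dosages_vcf(paths$vcf)
  if (!is.null(paths$weights)) out$weights <- read_weights(paths$weights)
  out
}

#' Write pipeline outputs
#'
#' Writes the association table (`assoc.tsv`, one row per variant x model),
#' the QC audit (`audit.json`) and a run manifest (`manifest.json`) echoing
#' the configuration and the master seed. Paths are checked before anything
#' is written.
#'
#' @param results association results data.frame (see [scan_variants()]).
#' @param audit a `qc_audit` object or `NULL`.
#' @param config list echoed into the manifest; must contain `seed`.
#' @param dir output directory, created if absent.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(results, audit, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0L) stop("output directory not writable: ", dir)
  paths <- c(assoc = file.path(dir, "assoc.tsv"),
             audit = file.path(dir, "audit.json"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.table(results, paths[["assoc"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(audit)) {
    jsonlite::write_json(unclass(audit), paths[["audit"]], auto_unbox = TRUE,
                         digits = NA)
  }
  jsonlite::write_json(list(package = "pgxresponse",
                            seed = config$seed, config = config),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}

#' Read back an association table written by [write_outputs()]
#' @param path path to `assoc.tsv`.
#' @return data.frame.
#' @export
read_assoc <- function(path) {
  read_tsv_checked(path, c("variant_id", "model", "mode", "beta", "se", "p", "n"),
                   "association table")
}

#' Read back a QC audit written by [write_outputs()]
#' @param path path to `audit.json`.
#' @return a `qc_audit` object.
#' @export
read_audit <- function(path) {
  a <- jsonlite::read_json(path, simplifyVector = TRUE)
  a$removed <- as.integer(a$removed)
  a$input_n <- as.integer(a$input_n)
  a$survivors <- as.integer(a$survivors)
  structure(a, class = "qc_audit")
}
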