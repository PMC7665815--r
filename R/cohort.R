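# Lesion-observation records: schema, construction, validation and CSV/TSV
# round trip. A cohort is a plain data.frame with one row per observation;
# ancillary-feature sets are encoded as semicolon-delimited token strings and
# an absent growth record as NA growth columns.

COHORT_COLUMNS <- c(
  "id", "diagnosis", "size_mm",
  "aphe_ordinary", "aphe_subtraction",
  "washout_pvp", "tp_hypointensity", "hbp_hypointensity", "enhancing_capsule",
  "growth_pct_increase", "growth_interval_months",
  "growth_new_nodule_ge10mm", "growth_unequivocal",
  "targetoid_other", "definite_benign", "probable_benign",
  "af_malignancy_general", "af_hcc_specific", "af_benign",
  "reader_category_override", "override_washout_dependent"
)

LOGICAL_COLUMNS <- c(
  "washout_pvp", "tp_hypointensity", "hbp_hypointensity", "enhancing_capsule",
  "growth_new_nodule_ge10mm", "growth_unequivocal",
  "targetoid_other", "definite_benign", "probable_benign",
  "override_washout_dependent"
)

#' Construct a single lesion-observation record
#'
#' Builds a one-row cohort data.frame with the full observation schema. All
#' imaging features default to absent, so only the findings present need to
#' be named; this is the unit from which test fixtures and examples are
#' assembled. Use `rbind()` to combine records into a cohort.
#'
#' @param id observation identifier (opaque string).
#' @param diagnosis reference diagnosis: `"HCC"`, `"NON_HCC_MALIGNANCY"` or
#'   `"BENIGN"`.
#' @param size_mm observation size in millimetres (> 0).
#' @param aphe_ordinary arterial-phase hyperenhancement as read on the
#'   ordinary late arterial phase: `"ABSENT"`, `"NONRIM"` or `"RIM"`.
#' @param aphe_subtraction enhancement pattern on the arterial-minus-
#'   precontrast subtraction image: `"ABSENT"`, `"GLOBAL"` or `"RIM"`.
#' @param washout_pvp nonperipheral washout in the portal venous phase.
#' @param tp_hypointensity hypointensity in the transitional phase.
#' @param hbp_hypointensity hepatobiliary-phase hypointensity.
#' @param enhancing_capsule enhancing capsule appearance.
#' @param growth_pct_increase percent size increase versus the prior exam
#'   (`NA` when no prior exam exists).
#' @param growth_interval_months interval to the prior exam in months (`NA`
#'   when no prior exam exists; must be > 0 otherwise).
#' @param growth_new_nodule_ge10mm new >= 10 mm nodule since the prior exam.
#' @param growth_unequivocal unequivocal size increase below threshold.
#' @param targetoid_other any non-APHE targetoid feature (peripheral
#'   washout, delayed central enhancement, targetoid restriction/TP/HBP).
#' @param definite_benign,probable_benign LR-1 / LR-2 gates.
#' @param af_malignancy_general semicolon-delimited tokens from
#'   `af_vocabulary()$malignancy_general`.
#' @param af_hcc_specific semicolon-delimited tokens from
#'   `af_vocabulary()$hcc_specific`.
#' @param af_benign semicolon-delimited free-vocabulary tokens for features
#'   favoring benignity (only emptiness is consulted).
#' @param reader_category_override reader-assigned category used in place of
#'   the engine output when present (`NA` for none).
#' @param override_washout_dependent whether the override was justified by
#'   washout without APHE (consulted by the no-washout-without-APHE variant).
#' @return one-row data.frame with the cohort schema.
#' @examples
#' obs <- lesion_observation(size_mm = 25, aphe_ordinary = "NONRIM",
#'                           washout_pvp = TRUE)
#' assign_category(obs)$category
#' @export
lesion_observation <- function(id = "OBS1",
                               diagnosis = "HCC",
                               size_mm = 30,
                               aphe_ordinary = "ABSENT",
                               aphe_subtraction = "ABSENT",
                               washout_pvp = FALSE,
                               tp_hypointensity = FALSE,
                               hbp_hypointensity = FALSE,
                               enhancing_capsule = FALSE,
                               growth_pct_increase = NA_real_,
                               growth_interval_months = NA_real_,
                               growth_new_nodule_ge10mm = FALSE,
                               growth_unequivocal = FALSE,
                               targetoid_other = FALSE,
                               definite_benign = FALSE,
                               probable_benign = FALSE,
                               af_malignancy_general = "",
                               af_hcc_specific = "",
                               af_benign = "",
                               reader_category_override = NA_character_,
                               override_washout_dependent = FALSE) {
  data.frame(
    id = as.character(id), diagnosis = diagnosis, size_mm = size_mm,
    aphe_ordinary = aphe_ordinary, aphe_subtraction = aphe_subtraction,
    washout_pvp = washout_pvp, tp_hypointensity = tp_hypointensity,
    hbp_hypointensity = hbp_hypointensity, enhancing_capsule = enhancing_capsule,
    growth_pct_increase = growth_pct_increase,
    growth_interval_months = growth_interval_months,
    growth_new_nodule_ge10mm = growth_new_nodule_ge10mm,
    growth_unequivocal = growth_unequivocal,
    targetoid_other = targetoid_other,
    definite_benign = definite_benign, probable_benign = probable_benign,
    af_malignancy_general = af_malignancy_general,
    af_hcc_specific = af_hcc_specific, af_benign = af_benign,
    reader_category_override = as.character(reader_category_override),
    override_washout_dependent = override_washout_dependent,
    stringsAsFactors = FALSE
  )
}

#' Validate a cohort of lesion observations
#'
#' Checks the schema and the record-level invariants: positive sizes, valid
#' enum values, ancillary-feature tokens drawn from the fixed vocabularies,
#' and consistency between ancillary features and the features they assert
#' (a `TP_HYPOINTENSITY` ancillary requires `tp_hypointensity`, an
#' `HBP_HYPOINTENSITY` ancillary requires `hbp_hypointensity`, and a
#' `SUBTHRESHOLD_GROWTH` ancillary requires a growth record). Observations
#' flagged as tumor-in-vein or previously treated (optional columns
#' `tumor_in_vein` / `treated`) are rejected, mirroring the upstream
#' exclusion of such lesions from category-based analysis.
#'
#' @param cohort data.frame with the columns of [lesion_observation()].
#' @return the cohort, invisibly normalised (logical coercion, `""` override
#'   mapped to `NA`). Errors name the offending field.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop("cohort must be a data.frame")
  missing_cols <- setdiff(COHORT_COLUMNS, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  cohort <- as.data.frame(cohort, stringsAsFactors = FALSE)
  for (col in LOGICAL_COLUMNS) {
    v <- cohort[[col]]
    if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
    v <- as.logical(v)
    v[is.na(v)] <- FALSE
    cohort[[col]] <- v
  }
  cohort$id <- as.character(cohort$id)
  ovr <- as.character(cohort$reader_category_override)
  ovr[!is.na(ovr) & !nzchar(ovr)] <- NA_character_
  cohort$reader_category_override <- ovr

  check_enum <- function(col, levels, allow_na = FALSE) {
    v <- cohort[[col]]
    bad <- !(v %in% levels) & !(allow_na & is.na(v))
    if (any(bad)) {
      stop(sprintf("invalid value(s) in field '%s': %s", col,
                   paste(unique(v[bad]), collapse = ", ")))
    }
  }
  check_enum("diagnosis", DIAGNOSIS_LEVELS)
  check_enum("aphe_ordinary", APHE_ORDINARY_LEVELS)
  check_enum("aphe_subtraction", APHE_SUBTRACTION_LEVELS)
  check_enum("reader_category_override", LR_CATEGORIES, allow_na = TRUE)

  if (any(!is.finite(cohort$size_mm) | cohort$size_mm <= 0)) {
    stop("invalid value(s) in field 'size_mm': sizes must be positive")
  }
  interval <- cohort$growth_interval_months
  if (any(!is.na(interval) & interval <= 0)) {
    stop("invalid value(s) in field 'growth_interval_months': intervals must be positive")
  }

  af_gen <- split_af(cohort$af_malignancy_general)
  af_hcc <- split_af(cohort$af_hcc_specific)
  bad_gen <- !vapply(af_gen, function(t) all(t %in% AF_MALIGNANCY_GENERAL), logical(1))
  if (any(bad_gen)) stop("unknown token(s) in field 'af_malignancy_general'")
  bad_hcc <- !vapply(af_hcc, function(t) all(t %in% AF_HCC_SPECIFIC), logical(1))
  if (any(bad_hcc)) stop("unknown token(s) in field 'af_hcc_specific'")

  has <- function(tokens, what) vapply(tokens, function(t) what %in% t, logical(1))
  if (any(has(af_gen, "TP_HYPOINTENSITY") & !cohort$tp_hypointensity)) {
    stop("field 'af_malignancy_general' lists TP_HYPOINTENSITY without tp_hypointensity")
  }
  if (any(has(af_gen, "HBP_HYPOINTENSITY") & !cohort$hbp_hypointensity)) {
    stop("field 'af_malignancy_general' lists HBP_HYPOINTENSITY without hbp_hypointensity")
  }
  growth_present <- !is.na(cohort$growth_interval_months)
  if (any(has(af_gen, "SUBTHRESHOLD_GROWTH") & !growth_present)) {
    stop("field 'af_malignancy_general' lists SUBTHRESHOLD_GROWTH without a growth record")
  }

  for (col in c("tumor_in_vein", "treated")) {
    if (col %in% names(cohort)) {
      v <- cohort[[col]]
      if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
      if (any(as.logical(v), na.rm = TRUE)) {
        stop(sprintf("field '%s': such observations are excluded from analysis", col))
      }
    }
  }
  invisible(cohort)
}

#' Read and write observation cohorts
#'
#' CSV (or TSV, chosen by file extension) round trip for cohort tables. The
#' header row carries the exact field names of the observation schema; set
#' fields are semicolon-delimited tokens and an absent growth record is an
#' empty cell in the growth columns.
#'
#' @param path file path; a `.tsv` extension selects tab separation.
#' @param cohort validated cohort data.frame.
#' @return `read_cohort()`: a validated cohort data.frame; `write_cohort()`:
#'   the path, invisibly.
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(COHORT_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- function(x) suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
  raw$size_mm <- num(raw$size_mm)
  raw$growth_pct_increase <- num(raw$growth_pct_increase)
  raw$growth_interval_months <- num(raw$growth_interval_months)
  validate_cohort(raw)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  out <- cohort[, COHORT_COLUMNS]
  out$reader_category_override[is.na(out$reader_category_override)] <- ""
  write.table(out, path, sep = sep, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
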