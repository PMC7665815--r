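# The LI-RADS v2018 categorization engine. Evaluation order:
#   1. benignity gates (LR-1 / LR-2)
#   2. targetoid gate (effective rim APHE or any other targetoid feature -> LR-M)
#   3. major-feature diagnostic table (effective APHE x size bin x additional
#      features: nonperipheral washout, enhancing capsule, threshold growth)
#   4. ancillary-feature adjustment (one step; upgrades capped at LR-4)
#   5. reader category override
# Size bins are half-open: <10, [10, 20), >=20 mm.

#' Assign LI-RADS v2018 categories to a cohort
#'
#' Runs the deterministic categorization engine over a cohort of lesion
#' observations. The interpretation parameters select between the standard
#' v2018 reading (the defaults) and the modified readings used by the
#' category-adjustment rules: washout may be extended to the transitional
#' phase, washout may be conditioned on the presence of wash-in (APHE),
#' arterial-phase hyperenhancement may be read on the subtraction image, and
#' growth may be graded under the v2017 dialect.
#'
#' With `aphe_source = "ORDINARY_OR_SUBTRACTION"`, a `GLOBAL` subtraction
#' pattern counts as nonrim APHE: it supplies APHE when the ordinary reading
#' is `ABSENT` and overrides a `RIM` ordinary reading (such observations
#' leave the targetoid gate and re-enter the major-feature pathway). A `RIM`
#' subtraction pattern never rescues anything.
#'
#' When a finding is promoted to a major feature by a modified reading, its
#' ancillary twin is dropped from the malignancy set for that evaluation so
#' a single finding is never counted twice: `TP_HYPOINTENSITY` is dropped
#' under `washout_def = "PVP_OR_TP"`, and `SUBTHRESHOLD_GROWTH` is dropped
#' for records grading `THRESHOLD` under the v2017 dialect.
#'
#' The ancillary step moves a category by at most one step: at least one
#' malignancy feature and no benignity feature upgrades (capped at LR-4 --
#' LR-5 is never reachable through ancillary features), at least one
#' benignity feature and no malignancy feature downgrades, and the presence
#' of both leaves the category unchanged. LR-1, LR-2 and LR-M exits are not
#' adjusted.
#'
#' @param cohort cohort data.frame (see [lesion_observation()]).
#' @param washout_def `"PVP_ONLY"` (default) or `"PVP_OR_TP"`.
#' @param washout_requires_aphe when `TRUE`, washout is disregarded in
#'   observations whose effective APHE is absent.
#' @param aphe_source `"ORDINARY"` (default) or `"ORDINARY_OR_SUBTRACTION"`.
#' @param growth_dialect `"V2018"` (default) or `"V2017"`.
#' @return data.frame with one row per observation: `id`, `category`,
#'   `pre_ancillary_category`, `major_feature_count` (0-3 additional
#'   features), `aphe_used`, `washout_used`, `upgraded_from_lr3` (category
#'   reached LR-4 only via ancillary upgrade), `override_applied`, and a
#'   `trace` string listing the rules that fired.
#' @examples
#' obs <- lesion_observation(size_mm = 30, washout_pvp = TRUE)
#' assign_category(obs)$category   # no APHE, >= 20 mm, one feature -> LR-4
#' @export
assign_category <- function(cohort,
                            washout_def = c("PVP_ONLY", "PVP_OR_TP"),
                            washout_requires_aphe = FALSE,
                            aphe_source = c("ORDINARY", "ORDINARY_OR_SUBTRACTION"),
                            growth_dialect = c("V2018", "V2017")) {
  washout_def <- match.arg(washout_def)
  aphe_source <- match.arg(aphe_source)
  growth_dialect <- match.arg(growth_dialect)
  stopifnot(is.logical(washout_requires_aphe), length(washout_requires_aphe) == 1)
  cohort <- validate_cohort(cohort)
  n <- nrow(cohort)

  # -- effective APHE ------------------------------------------------------
  eff_aphe <- cohort$aphe_ordinary
  if (aphe_source == "ORDINARY_OR_SUBTRACTION") {
    eff_aphe[cohort$aphe_subtraction == "GLOBAL"] <- "NONRIM"
  }
  aphe <- eff_aphe == "NONRIM"
  targetoid <- eff_aphe == "RIM" | cohort$targetoid_other

  # -- major features ------------------------------------------------------
  growth_state <- classify_growth(
    cohort$growth_pct_increase, cohort$growth_interval_months,
    cohort$growth_new_nodule_ge10mm, cohort$growth_unequivocal,
    dialect = growth_dialect
  )
  threshold_growth <- growth_state == "THRESHOLD"
  washout <- cohort$washout_pvp
  if (washout_def == "PVP_OR_TP") washout <- washout | cohort$tp_hypointensity
  if (washout_requires_aphe) washout <- washout & aphe
  capsule <- cohort$enhancing_capsule
  nfeat <- as.integer(washout) + as.integer(capsule) + as.integer(threshold_growth)

  size <- cohort$size_mm
  bin <- ifelse(size < 10, "lt10", ifelse(size < 20, "10to19", "ge20"))

  pre <- character(n)
  no_aphe <- !aphe
  pre[no_aphe & bin != "ge20"] <- ifelse(nfeat[no_aphe & bin != "ge20"] >= 2, "LR-4", "LR-3")
  pre[no_aphe & bin == "ge20"] <- ifelse(nfeat[no_aphe & bin == "ge20"] >= 1, "LR-4", "LR-3")
  pre[aphe & bin == "lt10"] <- ifelse(nfeat[aphe & bin == "lt10"] >= 1, "LR-4", "LR-3")
  mid <- aphe & bin == "10to19"
  pre[mid] <- ifelse(nfeat[mid] == 0, "LR-3",
                     ifelse(washout[mid] | threshold_growth[mid], "LR-5", "LR-4"))
  pre[aphe & bin == "ge20"] <- ifelse(nfeat[aphe & bin == "ge20"] >= 1, "LR-5", "LR-4")

  # -- ancillary adjustment ------------------------------------------------
  af_gen <- split_af(cohort$af_malignancy_general)
  af_hcc <- split_af(cohort$af_hcc_specific)
  af_ben <- split_af(cohort$af_benign)
  # a finding promoted to a major feature loses its ancillary role
  if (washout_def == "PVP_OR_TP") {
    af_gen <- lapply(af_gen, setdiff, "TP_HYPOINTENSITY")
  }
  if (growth_dialect == "V2017") {
    af_gen[threshold_growth] <- lapply(af_gen[threshold_growth], setdiff, "SUBTHRESHOLD_GROWTH")
  }
  n_mal <- lengths(af_gen) + lengths(af_hcc)
  has_ben <- lengths(af_ben) > 0
  upgrade <- n_mal > 0 & !has_ben
  downgrade <- has_ben & n_mal == 0

  rank <- match(pre, LR_ORDINAL)
  adj_rank <- rank
  adj_rank[upgrade] <- pmax(rank[upgrade], pmin(rank[upgrade] + 1L, 4L))
  adj_rank[downgrade] <- pmax(rank[downgrade] - 1L, 1L)
  adjusted <- LR_ORDINAL[adj_rank]
  upgraded_from_lr3 <- upgrade & pre == "LR-3" & adjusted == "LR-4"

  # -- assemble in evaluation order ---------------------------------------
  category <- character(n)
  trace <- character(n)
  gate1 <- cohort$definite_benign
  gate2 <- !gate1 & cohort$probable_benign
  gate_m <- !gate1 & !gate2 & targetoid
  table_path <- !gate1 & !gate2 & !gate_m

  category[gate1] <- "LR-1"
  trace[gate1] <- "gate:definite_benign"
  category[gate2] <- "LR-2"
  trace[gate2] <- "gate:probable_benign"
  category[gate_m] <- "LR-M"
  trace[gate_m] <- ifelse(eff_aphe[gate_m] == "RIM",
                          "gate:targetoid_rim_aphe", "gate:targetoid_other")
  category[table_path] <- adjusted[table_path]
  af_note <- ifelse(upgrade, "af:upgrade",
                    ifelse(downgrade, "af:downgrade",
                           ifelse(has_ben, "af:conflict", "af:none")))
  trace[table_path] <- paste0(
    "table:aphe=", as.integer(aphe[table_path]),
    ",bin=", bin[table_path],
    ",features=", nfeat[table_path],
    ";", af_note[table_path]
  )

  ovr <- !is.na(cohort$reader_category_override)
  category[ovr] <- cohort$reader_category_override[ovr]
  trace[ovr] <- paste0(trace[ovr], ";override:", category[ovr])

  data.frame(
    id = cohort$id,
    category = category,
    pre_ancillary_category = ifelse(table_path, pre, category),
    major_feature_count = nfeat,
    aphe_used = aphe & table_path,
    washout_used = washout & table_path,
    upgraded_from_lr3 = upgraded_from_lr3 & table_path,
    override_applied = ovr,
    trace = trace,
    stringsAsFactors = FALSE
  )
}

# Literal transcription of the v2018 diagnostic table, cell by cell. Kept
# free of the engine's conditional logic so it can serve as an independent
# cross-check of the major-feature pathway.
lirads_table <- local({
  combos <- c("", "washout", "capsule", "threshold_growth",
              "washout+capsule", "washout+threshold_growth",
              "capsule+threshold_growth", "washout+capsule+threshold_growth")
  cell <- function(aphe, bin, cats) {
    data.frame(aphe = aphe, bin = bin, features = combos, category = cats,
               stringsAsFactors = FALSE)
  }
  rbind(
    cell(FALSE, "lt10",   c("LR-3", "LR-3", "LR-3", "LR-3", "LR-4", "LR-4", "LR-4", "LR-4")),
    cell(FALSE, "10to19", c("LR-3", "LR-3", "LR-3", "LR-3", "LR-4", "LR-4", "LR-4", "LR-4")),
    cell(FALSE, "ge20",   c("LR-3", "LR-4", "LR-4", "LR-4", "LR-4", "LR-4", "LR-4", "LR-4")),
    cell(TRUE,  "lt10",   c("LR-3", "LR-4", "LR-4", "LR-4", "LR-4", "LR-4", "LR-4", "LR-4")),
    cell(TRUE,  "10to19", c("LR-3", "LR-5", "LR-4", "LR-5", "LR-5", "LR-5", "LR-5", "LR-5")),
    cell(TRUE,  "ge20",   c("LR-4", "LR-5", "LR-5", "LR-5", "LR-5", "LR-5", "LR-5", "LR-5"))
  )
})

#' Direct lookup of the v2018 major-feature diagnostic table
#'
#' Returns the category for one cell of the diagnostic table by direct
#' lookup of a literal transcription (2 APHE states x 3 size bins x every
#' composition of the additional features). This function deliberately
#' shares no logic with [assign_category()]; it exists so the engine's
#' major-feature pathway can be verified by exhaustive comparison.
#'
#' @param aphe logical: nonrim arterial-phase hyperenhancement present.
#' @param size_mm size in millimetres (bins: <10, 10-19.9, >= 20).
#' @param features character vector, subset of
#'   `c("washout", "capsule", "threshold_growth")`.
#' @return a category string (`"LR-3"`, `"LR-4"` or `"LR-5"`).
#' @examples
#' lirads_table_lookup(FALSE, 25, "washout")
#' lirads_table_lookup(TRUE, 15, "capsule")
#' @export
lirads_table_lookup <- function(aphe, size_mm, features = character()) {
  stopifnot(is.logical(aphe), length(aphe) == 1, size_mm > 0)
  allowed <- c("washout", "capsule", "threshold_growth")
  if (!all(features %in% allowed)) {
    stop("features must be a subset of: ", paste(allowed, collapse = ", "))
  }
  bin <- if (size_mm < 10) "lt10" else if (size_mm < 20) "10to19" else "ge20"
  key <- paste(allowed[allowed %in% features], collapse = "+")
  hit <- lirads_table$aphe == aphe & lirads_table$bin == bin & lirads_table$features == key
  lirads_table$category[hit]
}
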