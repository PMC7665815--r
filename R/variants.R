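# The six category-adjustment conditions. C1/C2 operate directly on the
# baseline assignments (LR-4 upgrades through ancillary features); C3-C6
# re-run the engine with one interpretation parameter changed. Conditions
# 3, 5 and 6 are one-directional relaxations: an observation never loses its
# baseline category merely because a finding changed role, so the
# recomputed ordinal category is floored at the baseline one.

VARIANT_IDS <- c(
  "BASELINE_LR5", "BASELINE_LR45",
  "C1_AF_MALIGNANCY", "C2_AF_HCC", "C3_SUBTRACTION_APHE",
  "C4_WASHOUT_REQUIRES_APHE", "C5_TP_WASHOUT", "C6_SUBTHRESHOLD_AS_THRESHOLD"
)
VARIANT_ALIASES <- c(
  c1 = "C1_AF_MALIGNANCY", c2 = "C2_AF_HCC", c3 = "C3_SUBTRACTION_APHE",
  c4 = "C4_WASHOUT_REQUIRES_APHE", c5 = "C5_TP_WASHOUT",
  c6 = "C6_SUBTHRESHOLD_AS_THRESHOLD",
  baseline = "BASELINE_LR5", baseline_lr45 = "BASELINE_LR45"
)

#' Identifiers of the category-adjustment conditions
#'
#' @return character vector of the recognised evaluation identifiers: the
#'   two baseline positivity rules and the six adjustment conditions.
#' @export
variant_ids <- function() VARIANT_IDS

normalize_variant <- function(variant) {
  stopifnot(is.character(variant), length(variant) == 1)
  v <- toupper(variant)
  if (v %in% VARIANT_IDS) return(v)
  alias <- VARIANT_ALIASES[tolower(variant)]
  if (!is.na(alias)) return(unname(alias))
  stop("unknown variant: ", variant,
       " (see variant_ids() for the recognised identifiers)")
}

#' Apply a category-adjustment condition to a baseline-categorized cohort
#'
#' Re-adjusts baseline LI-RADS categories under one of six conditions and
#' returns the adjusted assignments together with a reclassification audit.
#'
#' * `C1_AF_MALIGNANCY`: every baseline LR-4 with at least one ancillary
#'   feature favoring malignancy (general or HCC-specific), no benignity
#'   feature, and whose LR-4 was not itself reached by an ancillary upgrade
#'   from LR-3, is upgraded to LR-5.
#' * `C2_AF_HCC`: as C1 but only the HCC-specific set qualifies.
#' * `C3_SUBTRACTION_APHE`: categories are recomputed with APHE read on the
#'   ordinary arterial phase or the subtraction image; LR-M observations
#'   whose subtraction pattern is `GLOBAL` re-enter the major-feature
#'   pathway.
#' * `C4_WASHOUT_REQUIRES_APHE`: categories are recomputed with washout
#'   disregarded when APHE is absent; reader-overridden LR-5 observations
#'   annotated as washout-dependent are demoted one category to LR-4.
#' * `C5_TP_WASHOUT`: categories are recomputed with washout extended to
#'   transitional-phase hypointensity (whose ancillary role is dropped for
#'   the evaluation).
#' * `C6_SUBTHRESHOLD_AS_THRESHOLD`: categories are recomputed with growth
#'   graded under the v2017 dialect (records promoted to threshold growth
#'   lose their subthreshold-growth ancillary for the evaluation).
#'
#' Variants are always evaluated independently from the same baseline
#' (conditions are never stacked). The baseline identifiers return the
#' assignments unchanged with an empty audit.
#'
#' @param cohort cohort data.frame, as categorized to produce `baseline`.
#' @param baseline assignments from [assign_category()] run with default
#'   parameters on `cohort`.
#' @param variant an identifier from [variant_ids()] (short aliases
#'   `"c1"`..`"c6"` are accepted).
#' @return list with `assignments` (same shape as `baseline`) and `audit`,
#'   a `reclassification_audit` holding the variant id, one row per changed
#'   observation (`id`, `from`, `to`, `reason`) and the transition counts.
#' @examples
#' cohort <- build_reference_cohort()
#' base <- assign_category(cohort)
#' c1 <- apply_variant(cohort, base, "c1")
#' nrow(c1$audit$moves)   # 91 LR-4 observations upgraded
#' @export
apply_variant <- function(cohort, baseline, variant) {
  variant <- normalize_variant(variant)
  cohort <- validate_cohort(cohort)
  if (!is.data.frame(baseline) || !all(c("id", "category") %in% names(baseline))) {
    stop("baseline must be an assignment data.frame from assign_category()")
  }
  if (nrow(baseline) != nrow(cohort) || !identical(as.character(baseline$id), cohort$id)) {
    stop("baseline assignments do not match the cohort (ids differ)")
  }

  new <- baseline
  reason <- rep(NA_character_, nrow(cohort))

  if (variant %in% c("BASELINE_LR5", "BASELINE_LR45")) {
    # identity evaluation; nothing to adjust
  } else if (variant %in% c("C1_AF_MALIGNANCY", "C2_AF_HCC")) {
    af_hcc <- split_af(cohort$af_hcc_specific)
    qualifying <- if (variant == "C1_AF_MALIGNANCY") {
      lengths(split_af(cohort$af_malignancy_general)) + lengths(af_hcc)
    } else {
      lengths(af_hcc)
    }
    blocked <- lengths(split_af(cohort$af_benign)) > 0
    eligible <- baseline$category == "LR-4" & !baseline$upgraded_from_lr3 &
      qualifying > 0 & !blocked
    new$category[eligible] <- "LR-5"
    reason[eligible] <- if (variant == "C1_AF_MALIGNANCY") {
      "af_upgrade_malignancy_general"
    } else {
      "af_upgrade_hcc_specific"
    }
  } else {
    recomputed <- switch(
      variant,
      C3_SUBTRACTION_APHE = assign_category(cohort, aphe_source = "ORDINARY_OR_SUBTRACTION"),
      C4_WASHOUT_REQUIRES_APHE = assign_category(cohort, washout_requires_aphe = TRUE),
      C5_TP_WASHOUT = assign_category(cohort, washout_def = "PVP_OR_TP"),
      C6_SUBTHRESHOLD_AS_THRESHOLD = assign_category(cohort, growth_dialect = "V2017")
    )
    if (variant %in% c("C3_SUBTRACTION_APHE", "C5_TP_WASHOUT", "C6_SUBTHRESHOLD_AS_THRESHOLD")) {
      # one-directional relaxation: never lose the baseline ordinal category
      floor_it <- !is.na(lr_rank(recomputed$category)) &
        !is.na(lr_rank(baseline$category)) &
        lr_rank(recomputed$category) < lr_rank(baseline$category)
      recomputed$category[floor_it] <- baseline$category[floor_it]
      recomputed$trace[floor_it] <- paste0(recomputed$trace[floor_it], ";floor:baseline")
    }
    if (variant == "C4_WASHOUT_REQUIRES_APHE") {
      demote <- recomputed$override_applied &
        !is.na(cohort$reader_category_override) &
        cohort$reader_category_override == "LR-5" &
        cohort$override_washout_dependent
      recomputed$category[demote] <- "LR-4"
      recomputed$trace[demote] <- paste0(recomputed$trace[demote], ";demote:washout_dependent_override")
    }
    changed <- recomputed$category != baseline$category
    reason[changed] <- switch(
      variant,
      C3_SUBTRACTION_APHE = "subtraction_aphe",
      C4_WASHOUT_REQUIRES_APHE = "washout_requires_aphe",
      C5_TP_WASHOUT = "tp_washout",
      C6_SUBTHRESHOLD_AS_THRESHOLD = "v2017_threshold_growth"
    )
    new <- recomputed
  }

  moved <- new$category != baseline$category
  moves <- data.frame(
    id = cohort$id[moved],
    category_before = baseline$category[moved],
    category_after = new$category[moved],
    reason = reason[moved],
    stringsAsFactors = FALSE
  )
  counts <- if (nrow(moves)) {
    aggregate(list(n = moves$id),
              by = list(from = moves$category_before, to = moves$category_after),
              FUN = length)
  } else {
    data.frame(from = character(), to = character(), n = integer(),
               stringsAsFactors = FALSE)
  }
  audit <- structure(
    list(variant = variant, moves = moves, counts_by_transition = counts),
    class = "reclassification_audit"
  )
  list(assignments = new, audit = audit)
}

#' @export
print.reclassification_audit <- function(x, ...) {
  cat("Reclassification audit:", x$variant, "\n")
  if (!nrow(x$moves)) {
    cat("  no category changes\n")
  } else {
    for (i in seq_len(nrow(x$counts_by_transition))) {
      with(x$counts_by_transition[i, ],
           cat(sprintf("  %s -> %s: %d\n", from, to, n)))
    }
  }
  invisible(x)
}

#' Positivity of assignments under an LR-5 or LR-4/5 rule
#'
#' @param assignments assignment data.frame from [assign_category()] (or a
#'   bare character vector of categories).
#' @param rule `"LR5_ONLY"` (default) or `"LR4_OR_LR5"`. LR-M is negative
#'   under both rules.
#' @return logical vector, one element per observation.
#' @examples
#' positivity(c("LR-5", "LR-M", "LR-4"), "LR5_ONLY")
#' @export
positivity <- function(assignments, rule = c("LR5_ONLY", "LR4_OR_LR5")) {
  rule <- match.arg(rule)
  category <- if (is.data.frame(assignments)) assignments$category else assignments
  if (rule == "LR5_ONLY") category == "LR-5" else category %in% c("LR-4", "LR-5")
}
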