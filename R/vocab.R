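# Controlled vocabulary shared across the package. Ancillary-feature tokens
# follow the LI-RADS v2018 lexicon; features favoring benignity are a free
# vocabulary (only emptiness/non-emptiness of the set is ever consulted).

LR_ORDINAL <- c("LR-1", "LR-2", "LR-3", "LR-4", "LR-5")
LR_CATEGORIES <- c(LR_ORDINAL, "LR-M")

DIAGNOSIS_LEVELS <- c("HCC", "NON_HCC_MALIGNANCY", "BENIGN")
APHE_ORDINARY_LEVELS <- c("ABSENT", "NONRIM", "RIM")
APHE_SUBTRACTION_LEVELS <- c("ABSENT", "GLOBAL", "RIM")
GROWTH_STATES <- c("NONE", "SUBTHRESHOLD", "THRESHOLD")

AF_MALIGNANCY_GENERAL <- c(
  "SUBTHRESHOLD_GROWTH", "RESTRICTED_DIFFUSION", "MILD_MODERATE_T2_HYPER",
  "CORONA_ENHANCEMENT", "FAT_SPARING", "IRON_SPARING",
  "TP_HYPOINTENSITY", "HBP_HYPOINTENSITY"
)
AF_HCC_SPECIFIC <- c(
  "NONENHANCING_CAPSULE", "NODULE_IN_NODULE", "MOSAIC",
  "BLOOD_PRODUCTS", "INTRALESIONAL_FAT"
)

#' LI-RADS category and ancillary-feature vocabulary
#'
#' `lr_categories()` returns the six category codes (`"LR-1"` to `"LR-5"`
#' plus the non-ordinal `"LR-M"`). `af_vocabulary()` returns the fixed token
#' sets for ancillary features favoring malignancy in general and favoring
#' HCC in particular. `lr_rank()` maps ordinal categories to ranks 1-5;
#' `"LR-M"` is deliberately mapped to `NA` because LR-M is never compared by
#' order with the ordinal categories.
#'
#' @param category character vector of category codes.
#' @return `lr_categories()`: character vector; `af_vocabulary()`: named list
#'   with elements `malignancy_general` and `hcc_specific`; `lr_rank()`:
#'   integer vector (`NA` for `"LR-M"` or unknown codes).
#' @examples
#' lr_rank(c("LR-3", "LR-5", "LR-M"))
#' @export
lr_categories <- function() LR_CATEGORIES

#' @rdname lr_categories
#' @export
af_vocabulary <- function() {
  list(malignancy_general = AF_MALIGNANCY_GENERAL, hcc_specific = AF_HCC_SPECIFIC)
}

#' @rdname lr_categories
#' @export
lr_rank <- function(category) match(category, LR_ORDINAL)

# Split a semicolon-delimited ancillary-feature field into token vectors.
split_af <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(tok) {
    tok <- trimws(tok)
    tok[nzchar(tok)]
  })
}

join_af <- function(tokens) vapply(tokens, paste, character(1), collapse = ";")
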