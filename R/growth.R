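#' Classify lesion growth under the v2018 or v2017 dialect
#'
#' Growth on serial imaging is graded as `"THRESHOLD"` (a major feature),
#' `"SUBTHRESHOLD"` (an ancillary feature favoring malignancy) or `"NONE"`.
#' Under v2018, threshold growth is a >= 50% size increase within <= 6
#' months; a >= 100% increase over more than 6 months and a new >= 10 mm
#' nodule within <= 24 months no longer qualify and are graded subthreshold,
#' as is any unequivocal below-threshold increase. Under the v2017 dialect
#' all three definitions count as threshold growth and only the unequivocal
#' below-threshold increase remains subthreshold.
#'
#' A record flagged as a new nodule is graded on that basis alone (the
#' percent increase is ignored). An absent record (`NA` interval) yields
#' `"NONE"`.
#'
#' @param pct_increase percent size increase versus the prior exam.
#' @param interval_months positive interval to the prior exam in months.
#' @param new_nodule_ge10mm logical, new >= 10 mm nodule.
#' @param unequivocal_increase logical, unequivocal increase below threshold.
#' @param dialect `"V2018"` (default) or `"V2017"`.
#' @return character vector over `c("NONE", "SUBTHRESHOLD", "THRESHOLD")`.
#' @examples
#' classify_growth(120, 8)                      # subthreshold under v2018
#' classify_growth(120, 8, dialect = "V2017")   # threshold under v2017
#' classify_growth(50, 6)                       # boundary is inclusive
#' @export
classify_growth <- function(pct_increase = NA_real_,
                            interval_months = NA_real_,
                            new_nodule_ge10mm = FALSE,
                            unequivocal_increase = FALSE,
                            dialect = c("V2018", "V2017")) {
  dialect <- match.arg(dialect)
  n <- max(length(pct_increase), length(interval_months),
           length(new_nodule_ge10mm), length(unequivocal_increase))
  pct <- rep_len(as.numeric(pct_increase), n)
  int <- rep_len(as.numeric(interval_months), n)
  new10 <- rep_len(as.logical(new_nodule_ge10mm), n)
  new10[is.na(new10)] <- FALSE
  uneq <- rep_len(as.logical(unequivocal_increase), n)
  uneq[is.na(uneq)] <- FALSE

  present <- !is.na(int)
  if (any(present & int <= 0)) stop("invalid growth record: interval_months must be positive")
  pct_known <- present & !is.na(pct) & !new10

  rapid <- pct_known & pct >= 50 & int <= 6
  late_doubling <- pct_known & pct >= 100 & int > 6
  new_nodule <- present & new10 & int <= 24

  out <- rep("NONE", n)
  if (dialect == "V2018") {
    threshold <- rapid
    subthr <- !threshold & present & (uneq | late_doubling | new_nodule)
  } else {
    threshold <- rapid | late_doubling | new_nodule
    subthr <- !threshold & present & uneq
  }
  out[subthr] <- "SUBTHRESHOLD"
  out[threshold] <- "THRESHOLD"
  out
}
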