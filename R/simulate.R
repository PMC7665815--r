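# Stochastic cohort simulator for property testing. The generative model
# draws a diagnosis class per observation and then class-conditional imaging
# features; record-level invariants (ancillary tokens implying their
# features) hold by construction. Default feature prevalences are those of
# the reference cohort.

default_class_params <- function() {
  list(
    HCC = list(
      # 81/508 no-APHE, 25/508 rim; washout 432/508; sizes around a
      # 29 mm median
      p_aphe = c(ABSENT = 81 / 508, NONRIM = 402 / 508, RIM = 25 / 508),
      p_sub_global = c(ABSENT = 16 / 81, NONRIM = 0.90, RIM = 0.04),
      p_washout_pvp = 432 / 508,
      p_tp_hypo = 0.25, p_hbp_hypo = 0.60, p_capsule = 0.20,
      p_targetoid_other = 0.01,
      p_growth_record = 0.10,
      growth_mix = c(threshold = 0.25, late_doubling = 0.40,
                     new_nodule = 0.10, unequivocal = 0.25),
      af_general = c(RESTRICTED_DIFFUSION = 0.45, MILD_MODERATE_T2_HYPER = 0.35,
                     CORONA_ENHANCEMENT = 0.05, FAT_SPARING = 0.02,
                     IRON_SPARING = 0.02),
      p_af_tp_given = 0.9, p_af_hbp_given = 0.8, p_af_subthr_given = 0.9,
      af_hcc = c(MOSAIC = 0.15, NODULE_IN_NODULE = 0.08,
                 NONENHANCING_CAPSULE = 0.06, BLOOD_PRODUCTS = 0.03,
                 INTRALESIONAL_FAT = 0.05),
      p_af_benign = 0.01,
      p_definite_benign = 0, p_probable_benign = 0,
      size_meanlog = log(29), size_sdlog = 0.55
    ),
    NON_HCC_MALIGNANCY = list(
      p_aphe = c(ABSENT = 0.10, NONRIM = 0.25, RIM = 0.65),
      p_sub_global = c(ABSENT = 0.05, NONRIM = 0.90, RIM = 0.02),
      p_washout_pvp = 0.25,
      p_tp_hypo = 0.30, p_hbp_hypo = 0.70, p_capsule = 0.05,
      p_targetoid_other = 0.30,
      p_growth_record = 0.10,
      growth_mix = c(threshold = 0.30, late_doubling = 0.30,
                     new_nodule = 0.10, unequivocal = 0.30),
      af_general = c(RESTRICTED_DIFFUSION = 0.60, MILD_MODERATE_T2_HYPER = 0.40,
                     CORONA_ENHANCEMENT = 0.03, FAT_SPARING = 0.01,
                     IRON_SPARING = 0.01),
      p_af_tp_given = 0.9, p_af_hbp_given = 0.8, p_af_subthr_given = 0.9,
      af_hcc = c(MOSAIC = 0.04, NODULE_IN_NODULE = 0.01,
                 NONENHANCING_CAPSULE = 0.02, BLOOD_PRODUCTS = 0.02,
                 INTRALESIONAL_FAT = 0.01),
      p_af_benign = 0.02,
      p_definite_benign = 0, p_probable_benign = 0,
      size_meanlog = log(36), size_sdlog = 0.50
    ),
    BENIGN = list(
      p_aphe = c(ABSENT = 0.80, NONRIM = 0.15, RIM = 0.05),
      p_sub_global = c(ABSENT = 0.02, NONRIM = 0.80, RIM = 0.02),
      p_washout_pvp = 0.05,
      p_tp_hypo = 0.05, p_hbp_hypo = 0.15, p_capsule = 0.01,
      p_targetoid_other = 0.05,
      p_growth_record = 0.02,
      growth_mix = c(threshold = 0.05, late_doubling = 0.10,
                     new_nodule = 0.15, unequivocal = 0.70),
      af_general = c(RESTRICTED_DIFFUSION = 0.05, MILD_MODERATE_T2_HYPER = 0.10,
                     CORONA_ENHANCEMENT = 0.01, FAT_SPARING = 0.01,
                     IRON_SPARING = 0.01),
      p_af_tp_given = 0.9, p_af_hbp_given = 0.8, p_af_subthr_given = 0.9,
      af_hcc = c(MOSAIC = 0.005, NODULE_IN_NODULE = 0.002,
                 NONENHANCING_CAPSULE = 0.002, BLOOD_PRODUCTS = 0.002,
                 INTRALESIONAL_FAT = 0.005),
      p_af_benign = 0.60,
      # LR-1/LR-2 gates at the reference cohort's benign rates
      p_definite_benign = 116 / 229, p_probable_benign = 52 / 229,
      size_meanlog = log(11), size_sdlog = 0.60
    )
  )
}

#' Simulation parameters for stochastic cohorts
#'
#' Assembles and validates the parameter object consumed by
#' [simulate_cohort()]: the cohort size, the diagnosis-class prevalences,
#' a random seed, and per-class feature probabilities (APHE pattern,
#' subtraction pattern conditional on the ordinary reading, washout,
#' transitional/hepatobiliary hypointensity, capsule, growth-record mix,
#' ancillary-feature inclusion rates and the LR-1/LR-2 gates). Defaults are
#' the feature prevalences of the reference cohort; override any subset via
#' `classes`.
#'
#' @param n number of observations.
#' @param prevalence named numeric vector of class prevalences over
#'   `c("HCC", "NON_HCC_MALIGNANCY", "BENIGN")`; must sum to 1.
#' @param seed integer random seed stored with the parameters.
#' @param classes named list of per-class parameter overrides, merged over
#'   the defaults.
#' @return object of class `simulation_params`.
#' @examples
#' p <- simulation_params(n = 100, seed = 7)
#' nrow(simulate_cohort(p))
#' @export
simulation_params <- function(n = 792,
                              prevalence = c(HCC = 508 / 792,
                                             NON_HCC_MALIGNANCY = 55 / 792,
                                             BENIGN = 229 / 792),
                              seed = 1L,
                              classes = list()) {
  stopifnot(n >= 1, is.numeric(prevalence))
  if (!setequal(names(prevalence), DIAGNOSIS_LEVELS)) {
    stop("prevalence must be named over: ", paste(DIAGNOSIS_LEVELS, collapse = ", "))
  }
  if (any(prevalence < 0) || abs(sum(prevalence) - 1) > 1e-8) {
    stop("prevalences must be non-negative and sum to 1")
  }
  base <- default_class_params()
  for (cls in names(classes)) {
    if (!cls %in% DIAGNOSIS_LEVELS) stop("unknown class in overrides: ", cls)
    for (field in names(classes[[cls]])) {
      if (!field %in% names(base[[cls]])) {
        stop("unknown parameter '", field, "' for class ", cls)
      }
      base[[cls]][[field]] <- classes[[cls]][[field]]
    }
  }
  for (cls in DIAGNOSIS_LEVELS) {
    p <- base[[cls]]
    probs <- c(p$p_aphe, p$p_sub_global, p$p_washout_pvp, p$p_tp_hypo,
               p$p_hbp_hypo, p$p_capsule, p$p_targetoid_other,
               p$p_growth_record, p$af_general, p$p_af_tp_given,
               p$p_af_hbp_given, p$p_af_subthr_given, p$af_hcc,
               p$p_af_benign, p$p_definite_benign, p$p_probable_benign)
    if (any(probs < 0 | probs > 1)) {
      stop("class ", cls, ": probabilities must lie in [0, 1]")
    }
    if (abs(sum(p$p_aphe) - 1) > 1e-8) {
      stop("class ", cls, ": p_aphe must sum to 1")
    }
  }
  structure(
    list(n = as.integer(n), prevalence = prevalence[DIAGNOSIS_LEVELS],
         seed = as.integer(seed), classes = base),
    class = "simulation_params"
  )
}

#' Simulate a stochastic observation cohort
#'
#' Draws `params$n` lesion observations from the class-conditional
#' generative model. The result is reproducible given the seed, every
#' record passes [validate_cohort()] by construction, and marginal feature
#' frequencies converge to the parameter values as `n` grows. Simulated
#' cohorts never carry reader category overrides.
#'
#' @param params a [simulation_params()] object.
#' @param seed optional seed overriding `params$seed` for this draw.
#' @return validated cohort data.frame of `params$n` rows.
#' @export
simulate_cohort <- function(params = simulation_params(), seed = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(if (is.null(seed)) params$seed else as.integer(seed))
  n <- params$n
  cls <- sample(DIAGNOSIS_LEVELS, n, replace = TRUE, prob = params$prevalence)

  draw <- function(p, k) runif(k) < p
  rows <- lapply(DIAGNOSIS_LEVELS, function(cl) {
    k <- sum(cls == cl)
    if (k == 0) return(NULL)
    p <- params$classes[[cl]]
    size <- pmax(rlnorm(k, p$size_meanlog, p$size_sdlog), 3)
    aphe <- sample(names(p$p_aphe), k, replace = TRUE, prob = p$p_aphe)
    sub <- ifelse(draw(p$p_sub_global[aphe], k), "GLOBAL",
                  ifelse(aphe == "RIM", "RIM", "ABSENT"))
    def_ben <- draw(p$p_definite_benign, k)
    prob_ben <- !def_ben & draw(p$p_probable_benign /
                                  max(1e-12, 1 - p$p_definite_benign), k)
    washout <- draw(p$p_washout_pvp, k)
    tp <- draw(p$p_tp_hypo, k)
    hbp <- draw(p$p_hbp_hypo, k)
    capsule <- draw(p$p_capsule, k)
    targetoid <- draw(p$p_targetoid_other, k)

    has_growth <- draw(p$p_growth_record, k)
    gtype <- sample(names(p$growth_mix), k, replace = TRUE, prob = p$growth_mix)
    pct <- rep(NA_real_, k); int <- rep(NA_real_, k)
    new10 <- rep(FALSE, k); uneq <- rep(FALSE, k)
    g <- has_growth & gtype == "threshold"
    pct[g] <- runif(sum(g), 50, 200); int[g] <- runif(sum(g), 1, 6)
    g <- has_growth & gtype == "late_doubling"
    pct[g] <- runif(sum(g), 100, 300); int[g] <- runif(sum(g), 7, 18)
    g <- has_growth & gtype == "new_nodule"
    new10[g] <- TRUE; pct[g] <- 0; int[g] <- runif(sum(g), 1, 24)
    g <- has_growth & gtype == "unequivocal"
    pct[g] <- runif(sum(g), 10, 45); int[g] <- runif(sum(g), 7, 24)
    uneq[g] <- TRUE

    pick_af <- function(rates, m) {
      hits <- matrix(runif(m * length(rates)) < rep(rates, each = m), nrow = m)
      apply(hits, 1, function(r) paste(names(rates)[r], collapse = ";"))
    }
    af_gen <- pick_af(p$af_general, k)
    add_token <- function(af, token, cond) {
      ifelse(cond, ifelse(nzchar(af), paste(af, token, sep = ";"), token), af)
    }
    growth_v2018 <- classify_growth(pct, int, new10, uneq)
    af_gen <- add_token(af_gen, "TP_HYPOINTENSITY", tp & draw(p$p_af_tp_given, k))
    af_gen <- add_token(af_gen, "HBP_HYPOINTENSITY", hbp & draw(p$p_af_hbp_given, k))
    af_gen <- add_token(af_gen, "SUBTHRESHOLD_GROWTH",
                        growth_v2018 == "SUBTHRESHOLD" & draw(p$p_af_subthr_given, k))
    af_hcc <- pick_af(p$af_hcc, k)
    af_ben <- ifelse(draw(p$p_af_benign, k), "FAVORS_BENIGNITY", "")

    data.frame(
      id = NA_character_, diagnosis = cl, size_mm = size,
      aphe_ordinary = aphe, aphe_subtraction = sub,
      washout_pvp = washout, tp_hypointensity = tp, hbp_hypointensity = hbp,
      enhancing_capsule = capsule,
      growth_pct_increase = pct, growth_interval_months = int,
      growth_new_nodule_ge10mm = new10, growth_unequivocal = uneq,
      targetoid_other = targetoid,
      definite_benign = def_ben, probable_benign = prob_ben,
      af_malignancy_general = af_gen, af_hcc_specific = af_hcc,
      af_benign = af_ben,
      reader_category_override = NA_character_,
      override_washout_dependent = FALSE,
      stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, rows)   # grouped by diagnosis class; deterministic
  cohort$id <- sprintf("SIM%05d", seq_len(nrow(cohort)))
  rownames(cohort) <- NULL
  validate_cohort(cohort)
  cohort
}
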