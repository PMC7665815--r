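# Shared fixtures for the test suite. The reference cohort is deterministic
# and cheap to build, so it is constructed once per test run.

ref_cohort <- build_reference_cohort()
ref_baseline <- assign_category(ref_cohort)

# Single-observation category, for terse engine checks.
category_of <- function(..., params = list()) {
  obs <- lesion_observation(...)
  do.call(assign_category, c(list(obs), params))$category
}

# Feature combinations of the major-feature table, as constructor arguments.
feature_args <- function(features) {
  args <- list()
  if ("washout" %in% features) args$washout_pvp <- TRUE
  if ("capsule" %in% features) args$enhancing_capsule <- TRUE
  if ("threshold_growth" %in% features) {
    args$growth_pct_increase <- 60
    args$growth_interval_months <- 4
  }
  args
}

all_feature_subsets <- local({
  feats <- c("washout", "capsule", "threshold_growth")
  unlist(lapply(0:3, function(k) combn(feats, k, simplify = FALSE)),
         recursive = FALSE)
})
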