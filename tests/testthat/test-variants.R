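test_that("ancillary-upgrade conditions move the expected fixture observations", {
  c1 <- apply_variant(ref_cohort, ref_baseline, "c1")
  moves <- c1$audit$moves
  expect_equal(nrow(moves), 91)
  expect_true(all(moves$category_before == "LR-4" & moves$category_after == "LR-5"))
  diag1 <- ref_cohort$diagnosis[match(moves$id, ref_cohort$id)]
  expect_equal(sum(diag1 == "HCC"), 83)
  expect_equal(sum(diag1 == "NON_HCC_MALIGNANCY"), 8)

  c2 <- apply_variant(ref_cohort, ref_baseline, "c2")
  diag2 <- ref_cohort$diagnosis[match(c2$audit$moves$id, ref_cohort$id)]
  expect_equal(nrow(c2$audit$moves), 37)
  expect_equal(sum(diag2 == "HCC"), 36)
  # HCC-specific upgrades are a subset of general-malignancy upgrades
  expect_true(all(c2$audit$moves$id %in% moves$id))
})

test_that("conditioning washout on APHE demotes exactly the washout-dependent LR-5s", {
  c4 <- apply_variant(ref_cohort, ref_baseline, "c4")
  lr5_moves <- c4$audit$moves[c4$audit$moves$category_before == "LR-5", ]
  expect_equal(nrow(lr5_moves), 3)
  expect_equal(lr5_moves$category_after, rep("LR-4", 3))
  expect_true(all(ref_cohort$diagnosis[match(lr5_moves$id, ref_cohort$id)] == "HCC"))
  # no observation ever gains a category under this condition
  r_new <- lr_rank(c4$assignments$category)
  r_old <- lr_rank(ref_baseline$category)
  keep <- !is.na(r_new) & !is.na(r_old)
  expect_true(all(r_new[keep] <= r_old[keep]))
})

test_that("a benignity feature or LR-3 provenance blocks the ancillary upgrade", {
  cohort <- rbind(
    lesion_observation("blocked", size_mm = 30, aphe_ordinary = "NONRIM",
                       af_malignancy_general = "RESTRICTED_DIFFUSION",
                       af_benign = "SIZE_STABILITY"),
    lesion_observation("from_lr3", size_mm = 15, aphe_ordinary = "NONRIM",
                       af_malignancy_general = "RESTRICTED_DIFFUSION"),
    lesion_observation("eligible", size_mm = 30, aphe_ordinary = "NONRIM",
                       af_malignancy_general = "RESTRICTED_DIFFUSION")
  )
  base <- assign_category(cohort)
  expect_equal(base$category, c("LR-4", "LR-4", "LR-4"))
  res <- apply_variant(cohort, base, "c1")
  expect_equal(res$assignments$category, c("LR-4", "LR-4", "LR-5"))
  expect_equal(res$audit$moves$id, "eligible")
})

test_that("positivity rules count LR-M as negative and match the fixture margins", {
  expect_equal(positivity(c("LR-5", "LR-M", "LR-4"), "LR5_ONLY"),
               c(TRUE, FALSE, FALSE))
  expect_equal(positivity(c("LR-5", "LR-M", "LR-4"), "LR4_OR_LR5"),
               c(TRUE, FALSE, TRUE))
  expect_equal(sum(positivity(ref_baseline, "LR5_ONLY")), 371)
  expect_equal(sum(positivity(ref_baseline, "LR4_OR_LR5")), 488)
})

test_that("variant evaluations satisfy their directional and structural invariants", {
  cohort <- simulate_cohort(simulation_params(n = 500, seed = 42))
  base <- assign_category(cohort)
  res <- lapply(setNames(paste0("c", 1:6), paste0("c", 1:6)),
                function(v) apply_variant(cohort, base, v))
  r_base <- lr_rank(base$category)

  # LR-1 / LR-2 observations are untouchable
  gated <- base$category %in% c("LR-1", "LR-2")
  for (v in names(res)) {
    expect_equal(res[[v]]$assignments$category[gated], base$category[gated],
                 label = paste(v, "on LR-1/LR-2"))
  }
  # C1 moves contain C2 moves
  expect_true(all(res$c2$audit$moves$id %in% res$c1$audit$moves$id))
  # relaxations never demote; the restriction never promotes
  for (v in c("c3", "c5", "c6")) {
    r_new <- lr_rank(res[[v]]$assignments$category)
    keep <- !is.na(r_new) & !is.na(r_base)
    expect_true(all(r_new[keep] >= r_base[keep]), label = paste(v, "monotone"))
  }
  r4 <- lr_rank(res$c4$assignments$category)
  keep <- !is.na(r4) & !is.na(r_base)
  expect_true(all(r4[keep] <= r_base[keep]))

  # idempotence: re-applying a variant to its own output changes nothing
  for (v in names(res)) {
    again <- apply_variant(cohort, res[[v]]$assignments, v)
    expect_equal(again$assignments$category, res[[v]]$assignments$category,
                 label = paste(v, "idempotent"))
    expect_equal(nrow(again$audit$moves), 0, label = paste(v, "idempotent audit"))
  }

  # audit conservation: positives after = before + inflow - outflow
  for (v in names(res)) {
    trans <- res[[v]]$audit$counts_by_transition
    inflow <- sum(trans$n[trans$to == "LR-5"])
    outflow <- sum(trans$n[trans$from == "LR-5"])
    expect_equal(sum(positivity(res[[v]]$assignments)),
                 sum(positivity(base)) + inflow - outflow,
                 label = paste(v, "conservation"))
  }
})

test_that("variant identifiers are validated before any computation", {
  expect_error(apply_variant(ref_cohort, ref_baseline, "c9"), "unknown variant")
  expect_setequal(
    variant_ids(),
    c("BASELINE_LR5", "BASELINE_LR45", "C1_AF_MALIGNANCY", "C2_AF_HCC",
      "C3_SUBTRACTION_APHE", "C4_WASHOUT_REQUIRES_APHE", "C5_TP_WASHOUT",
      "C6_SUBTHRESHOLD_AS_THRESHOLD")
  )
  # baseline identifiers are identity evaluations
  idn <- apply_variant(ref_cohort, ref_baseline, "BASELINE_LR5")
  expect_equal(idn$assignments$category, ref_baseline$category)
  expect_equal(nrow(idn$audit$moves), 0)
})
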