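test_that("worked single-observation categorizations are reproduced", {
  # no APHE but portal venous washout at 30 mm: one feature, LR-4
  expect_equal(category_of(size_mm = 30, washout_pvp = TRUE), "LR-4")
  # rim APHE is targetoid
  expect_equal(category_of(size_mm = 23, aphe_ordinary = "RIM"), "LR-M")
  # the same lesion re-read with a global subtraction pattern and threshold
  # growth re-enters the major-feature pathway and reaches LR-5
  expect_equal(
    category_of(size_mm = 23, aphe_ordinary = "RIM", aphe_subtraction = "GLOBAL",
                growth_pct_increase = 60, growth_interval_months = 4,
                params = list(aphe_source = "ORDINARY_OR_SUBTRACTION")),
    "LR-5"
  )
  # a global subtraction pattern with an absent ordinary reading counts as
  # nonrim APHE only when the subtraction source is enabled
  expect_equal(
    category_of(size_mm = 30, washout_pvp = TRUE, aphe_subtraction = "GLOBAL",
                params = list(aphe_source = "ORDINARY_OR_SUBTRACTION")),
    "LR-5"
  )
  expect_equal(
    category_of(size_mm = 30, washout_pvp = TRUE, aphe_subtraction = "GLOBAL"),
    "LR-4"
  )
  # a rim subtraction pattern never rescues anything
  expect_equal(
    category_of(size_mm = 23, aphe_ordinary = "RIM", aphe_subtraction = "RIM",
                params = list(aphe_source = "ORDINARY_OR_SUBTRACTION")),
    "LR-M"
  )
  # APHE with washout at >= 20 mm is LR-5; without washout LR-4
  expect_equal(category_of(size_mm = 25, aphe_ordinary = "NONRIM",
                           washout_pvp = TRUE), "LR-5")
  expect_equal(category_of(size_mm = 25, aphe_ordinary = "NONRIM"), "LR-4")
  # the 10-19 mm one-feature cell splits: capsule alone LR-4, washout LR-5
  expect_equal(category_of(size_mm = 15, aphe_ordinary = "NONRIM",
                           enhancing_capsule = TRUE), "LR-4")
  expect_equal(category_of(size_mm = 15, aphe_ordinary = "NONRIM",
                           washout_pvp = TRUE), "LR-5")
})

test_that("benignity and targetoid gates precede the diagnostic table", {
  expect_equal(category_of(definite_benign = TRUE, size_mm = 30,
                           washout_pvp = TRUE), "LR-1")
  expect_equal(category_of(probable_benign = TRUE), "LR-2")
  expect_equal(category_of(targetoid_other = TRUE, size_mm = 30,
                           aphe_ordinary = "NONRIM", washout_pvp = TRUE), "LR-M")
})

test_that("engine table pathway agrees with the direct transcription on the full grid", {
  for (aphe in c(FALSE, TRUE)) {
    for (size in c(5, 15, 25)) {
      for (features in all_feature_subsets) {
        args <- c(list(size_mm = size,
                       aphe_ordinary = if (aphe) "NONRIM" else "ABSENT"),
                  feature_args(features))
        got <- do.call(category_of, args)
        expect_equal(
          got, lirads_table_lookup(aphe, size, features),
          label = sprintf("aphe=%s size=%d {%s}: %s", aphe, size,
                          paste(features, collapse = ","), got)
        )
      }
    }
  }
})

test_that("without effective APHE the pre-ancillary category is never LR-5", {
  for (size in c(5, 15, 25)) {
    for (features in all_feature_subsets) {
      args <- c(list(size_mm = size), feature_args(features))
      obs <- do.call(lesion_observation, args)
      expect_false(assign_category(obs)$pre_ancillary_category == "LR-5")
    }
  }
})

test_that("adding a major feature never lowers the pre-ancillary category", {
  extra <- list(washout = c(washout_pvp = TRUE),
                capsule = c(enhancing_capsule = TRUE))
  for (aphe in c(FALSE, TRUE)) {
    for (size in c(5, 15, 25)) {
      for (features in all_feature_subsets) {
        base_args <- c(list(size_mm = size,
                            aphe_ordinary = if (aphe) "NONRIM" else "ABSENT"),
                       feature_args(features))
        base_rank <- lr_rank(do.call(category_of, base_args))
        for (add in setdiff(c("washout", "capsule", "threshold_growth"), features)) {
          more_args <- c(list(size_mm = size,
                              aphe_ordinary = if (aphe) "NONRIM" else "ABSENT"),
                         feature_args(union(features, add)))
          expect_gte(lr_rank(do.call(category_of, more_args)), base_rank)
        }
      }
    }
  }
})

test_that("ancillary features move one step, are capped at LR-4 and log provenance", {
  # upgrade LR-3 -> LR-4 sets the provenance flag
  a <- assign_category(lesion_observation(size_mm = 15, aphe_ordinary = "NONRIM",
                                          af_malignancy_general = "RESTRICTED_DIFFUSION"))
  expect_equal(a$category, "LR-4")
  expect_equal(a$pre_ancillary_category, "LR-3")
  expect_true(a$upgraded_from_lr3)
  # LR-4 stays LR-4 (LR-5 unreachable through ancillary features)
  expect_equal(category_of(size_mm = 30, aphe_ordinary = "NONRIM",
                           af_hcc_specific = "MOSAIC"), "LR-4")
  # LR-5 from major features is left alone
  expect_equal(category_of(size_mm = 30, aphe_ordinary = "NONRIM",
                           washout_pvp = TRUE,
                           af_malignancy_general = "RESTRICTED_DIFFUSION"), "LR-5")
  # a benignity feature alone downgrades
  expect_equal(category_of(size_mm = 15, aphe_ordinary = "NONRIM",
                           af_benign = "SIZE_STABILITY"), "LR-2")
  # conflicting ancillary features cancel
  expect_equal(category_of(size_mm = 15, aphe_ordinary = "NONRIM",
                           af_malignancy_general = "RESTRICTED_DIFFUSION",
                           af_benign = "SIZE_STABILITY"), "LR-3")
})

test_that("reader overrides replace the engine category and are flagged", {
  a <- assign_category(lesion_observation(size_mm = 30, washout_pvp = TRUE,
                                          reader_category_override = "LR-5"))
  expect_equal(a$category, "LR-5")
  expect_equal(a$pre_ancillary_category, "LR-4")
  expect_true(a$override_applied)
})

test_that("categorization is deterministic and validation errors name the field", {
  obs <- ref_cohort
  expect_identical(assign_category(obs), assign_category(obs))
  bad <- lesion_observation(); bad$aphe_ordinary <- "WEAK"
  expect_error(assign_category(bad), "aphe_ordinary")
  bad <- lesion_observation(); bad$size_mm <- -2
  expect_error(assign_category(bad), "size_mm")
  bad <- lesion_observation(); bad$diagnosis <- "OTHER"
  expect_error(assign_category(bad), "diagnosis")
  # tumor-in-vein observations are rejected at validation
  tiv <- lesion_observation(); tiv$tumor_in_vein <- TRUE
  expect_error(assign_category(tiv), "tumor_in_vein")
  # ancillary tokens must be consistent with the features they assert
  bad <- lesion_observation(af_malignancy_general = "TP_HYPOINTENSITY")
  expect_error(assign_category(bad), "TP_HYPOINTENSITY")
})
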