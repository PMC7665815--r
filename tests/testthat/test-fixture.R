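test_that("the reference cohort satisfies every hard constraint", {
  report <- suppressMessages(validate_constraints(ref_cohort))
  expect_true(attr(report, "hard_ok"))
  hard <- report[report$severity == "HARD", ]
  expect_true(all(hard$pass))
  # exactly the four narrative counts known to conflict with the table
  # arithmetic deviate, and nothing else
  soft_fail <- report$id[!report$pass]
  expect_setequal(soft_fail, c("narrative_baseline_lr4", "narrative_baseline_lr5",
                               "narrative_c1_eligible_lr4", "narrative_c3_lr4_to_lr5"))
})

test_that("the reconstruction is deterministic and its margins are as published", {
  again <- build_reference_cohort()
  expect_identical(ref_cohort, again)
  expect_equal(nrow(ref_cohort), 792)
  expect_equal(as.vector(table(ref_cohort$diagnosis)[c("HCC", "NON_HCC_MALIGNANCY", "BENIGN")]),
               c(508, 55, 229))
  # HCC size distribution: 5 under 10 mm, 90 at 10-19 mm, 413 at >= 20 mm
  hcc_size <- ref_cohort$size_mm[ref_cohort$diagnosis == "HCC"]
  expect_equal(sum(hcc_size < 10), 5)
  expect_equal(sum(hcc_size >= 10 & hcc_size < 20), 90)
  expect_equal(sum(hcc_size >= 20), 413)
})

test_that("perturbing one record breaks exactly the affected constraints", {
  mutated <- ref_cohort
  i <- which(mutated$diagnosis == "HCC" & ref_baseline$category == "LR-5")[1]
  mutated$diagnosis[i] <- "BENIGN"
  report <- suppressMessages(validate_constraints(mutated, quiet = TRUE))
  failed <- report$id[!report$pass & report$severity == "HARD"]
  expect_true("hcc_total" %in% failed)
  expect_true("benign_total" %in% failed)
  expect_true("baseline_lr5_hcc" %in% failed)
  # category margins are untouched by a diagnosis flip
  expect_true(report$pass[report$id == "baseline_lr5"])
  expect_false(attr(report, "hard_ok"))
})

test_that("an empty cohort fails every non-zero count constraint", {
  empty <- ref_cohort[0, ]
  report <- suppressMessages(validate_constraints(empty, quiet = TRUE))
  expect_false(attr(report, "hard_ok"))
  expect_true(all(!report$pass[report$expected > 0]))
})

test_that("every published 2x2 cell is recomputed from features, not stored", {
  # the cohort carries no category columns; categories only ever arise by
  # running the engine
  expect_false(any(c("category", "baseline_category") %in% names(ref_cohort)))
  # spot-check one derived cell end to end: the no-APHE HCCs with washout
  no_aphe <- ref_cohort$diagnosis == "HCC" & ref_cohort$aphe_ordinary == "ABSENT"
  expect_equal(sum(no_aphe), 81)
  expect_equal(sum(no_aphe & ref_cohort$washout_pvp), 77)
})
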