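test_that("confusion tables cross-tabulate positivity against HCC truth", {
  truth <- ref_cohort$diagnosis
  ct <- confusion(positivity(ref_baseline, "LR5_ONLY"), truth)
  expect_equal(unclass(ct)[c("tp", "fp", "fn", "tn")],
               list(tp = 365, fp = 6, fn = 143, tn = 278))
  ct45 <- confusion(positivity(ref_baseline, "LR4_OR_LR5"), truth)
  expect_equal(unclass(ct45)[c("tp", "fp", "fn", "tn")],
               list(tp = 472, fp = 16, fn = 36, tn = 268))
  none <- confusion(rep(FALSE, nrow(ref_cohort)), truth)
  expect_equal(unclass(none)[c("tp", "fp", "fn", "tn")],
               list(tp = 0, fp = 0, fn = 508, tn = 284))
  expect_error(confusion(TRUE, c("HCC", "BENIGN")), "length")
})

test_that("accuracy metrics and their exact intervals match the reference row", {
  ct <- confusion(positivity(ref_baseline), ref_cohort$diagnosis)
  rep_ <- dta_metrics(ct)
  est <- setNames(rep_$metrics$estimate, rep_$metrics$metric)
  expect_equal(round(unname(est), 3),
               c(0.719, 0.979, 0.984, 0.660, 0.812))
  sens_row <- rep_$metrics[rep_$metrics$metric == "sensitivity", ]
  expect_equal(round(100 * c(sens_row$lower, sens_row$upper), 1), c(67.7, 75.7))
  # perfect and degenerate tables
  perfect <- structure(list(tp = 1, fp = 0, fn = 0, tn = 1), class = "confusion_table")
  pm <- dta_metrics(perfect)
  expect_equal(pm$metrics$estimate, rep(1, 5))
  no_neg <- structure(list(tp = 5, fp = 0, fn = 2, tn = 0), class = "confusion_table")
  nm <- dta_metrics(no_neg)
  expect_false(nm$metrics$defined[nm$metrics$metric == "specificity"])
  expect_true(nm$metrics$defined[nm$metrics$metric == "sensitivity"])
})

test_that("Clopper-Pearson bounds agree with direct inversion of the binomial test", {
  # independent oracle: invert the exact tail probabilities by root finding
  cp_oracle <- function(x, n, alpha = 0.05) {
    lower <- if (x == 0) 0 else
      uniroot(function(p) pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    upper <- if (x == n) 1 else
      uniroot(function(p) pbinom(x, n, p) - alpha / 2,
              c(1e-12, 1 - 1e-12), tol = 1e-12)$root
    c(lower, upper)
  }
  for (case in list(c(0, 10), c(10, 10), c(3, 17), c(365, 508), c(278, 284))) {
    got <- clopper_pearson(case[1], case[2])
    expect_equal(as.numeric(got), cp_oracle(case[1], case[2]), tolerance = 1e-9,
                 label = sprintf("CP(%d, %d)", case[1], case[2]))
  }
  # frozen closed-form anchors: (1 - u)^10 = 0.025 at x = 0, and symmetry
  expect_equal(clopper_pearson(0, 10)[, "upper"], 0.3084971, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(clopper_pearson(10, 10)[, "lower"], 1 - 0.3084971,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(clopper_pearson(11, 10), "x must")
  expect_error(clopper_pearson(2, 0), "n must")
})

test_that("exact McNemar reproduces the binomial tail and its symmetries", {
  expect_equal(mcnemar_exact(3, 0), 0.25)
  expect_equal(mcnemar_exact(8, 0), 0.0078125)
  expect_equal(mcnemar_exact(0, 0), 1)
  # enumeration oracle at b = c: 2 * sum of the lower binomial tail, capped
  expect_equal(mcnemar_exact(5, 5), min(1, 2 * sum(dbinom(0:5, 10, 0.5))))
  # symmetry and monotonicity in |b - c| at fixed b + c
  for (b in 0:6) expect_equal(mcnemar_exact(b, 6 - b), mcnemar_exact(6 - b, b))
  ps <- vapply(0:5, function(b) mcnemar_exact(b, 10 - b), numeric(1))
  expect_true(all(diff(ps) >= 0))  # p rises as the split evens out
  # the asymptotic form is available but differs
  expect_lt(abs(mcnemar_exact(8, 0, method = "asymptotic") - 0.0047), 1e-3)
})

test_that("the two-point AUC equals the average of sensitivity and specificity", {
  truth <- ref_cohort$diagnosis
  pos <- positivity(ref_baseline)
  ct <- confusion(pos, truth)
  sens <- ct$tp / (ct$tp + ct$fn)
  spec <- ct$tn / (ct$tn + ct$fp)
  expect_equal(binary_roc_auc(pos, truth), (sens + spec) / 2, tolerance = 1e-13)
  expect_equal(round(binary_roc_auc(pos, truth), 3), 0.849)
  expect_equal(round(binary_roc_auc(positivity(ref_baseline, "LR4_OR_LR5"), truth), 3),
               0.936)
  expect_error(binary_roc_auc(c(TRUE, FALSE), c("HCC", "HCC")), "degenerate")
})

test_that("paired DeLong comparison matches the independent pROC implementation", {
  set.seed(11)
  truth <- sample(c("HCC", "BENIGN"), 60, replace = TRUE, prob = c(0.6, 0.4))
  pos1 <- (truth == "HCC" & runif(60) < 0.8) | runif(60) < 0.15
  pos2 <- (truth == "HCC" & runif(60) < 0.6) | runif(60) < 0.10
  got <- delong_paired(pos1, pos2, truth)
  oracle <- pROC::roc.test(
    pROC::roc(truth == "HCC", as.numeric(pos1), quiet = TRUE),
    pROC::roc(truth == "HCC", as.numeric(pos2), quiet = TRUE),
    method = "delong", paired = TRUE
  )
  expect_equal(got$p_delong, oracle$p.value, tolerance = 1e-9)
  expect_equal(got$delta_auc,
               as.numeric(oracle$estimate[1] - oracle$estimate[2]),
               tolerance = 1e-12)
})

test_that("paired comparisons handle identity and report discordant pairs", {
  truth <- ref_cohort$diagnosis
  pos <- positivity(ref_baseline)
  same <- delong_paired(pos, pos, truth)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p_delong, 1)
  expect_equal(same$p_mcnemar, 1)
  # baseline vs the general-malignancy upgrade: reported AUC gain ~0.067
  c1_pos <- positivity(apply_variant(ref_cohort, ref_baseline, "c1")$assignments)
  cmp <- delong_paired(c1_pos, pos, truth, compare = "sensitivity")
  expect_equal(cmp$delta_auc,
               binary_roc_auc(c1_pos, truth) - binary_roc_auc(pos, truth),
               tolerance = 1e-12)
  expect_equal(round(cmp$delta_auc, 2), 0.07)
  expect_lt(cmp$p_delong, 0.001)
  expect_equal(c(cmp$b, cmp$c), c(83, 0))
  spec_cmp <- delong_paired(c1_pos, pos, truth, compare = "specificity")
  expect_equal(c(spec_cmp$b, spec_cmp$c), c(8, 0))
  expect_equal(spec_cmp$p_mcnemar, 0.0078125)
  expect_error(delong_paired(pos, pos[-1], truth), "length")
})
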