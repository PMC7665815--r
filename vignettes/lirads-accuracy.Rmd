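---
title: "Category-adjusted LR-5: the rule engine, the reference cohort and the accuracy statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-adjusted LR-5: the rule engine, the reference cohort and the accuracy statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liradscat)
```

## The problem

LI-RADS assigns each hepatic observation in an at-risk patient an ordinal
category LR-1 (definitely benign) to LR-5 (definitely HCC), plus the
non-ordinal LR-M for targetoid lesions. LR-5 supports a noninvasive HCC
diagnosis, so its operating point matters: under v2018 it is highly
specific but insensitive. This package studies, on a fully reconstructed
cohort, how six modified interpretation rules shift that operating point,
and provides the paired statistics needed to compare the adjusted rules
with the original on the same patients.

## The categorization engine

`assign_category()` evaluates each observation in a fixed order:

1. **Benignity gates.** `definite_benign` yields LR-1, otherwise
   `probable_benign` yields LR-2.
2. **Targetoid gate.** Effective rim APHE or any other targetoid feature
   yields LR-M.
3. **Major-feature table.** Effective nonrim APHE, the size bin and the
   count/composition of additional features (nonperipheral washout,
   enhancing capsule, threshold growth) index the v2018 diagnostic table.
4. **Ancillary adjustment.** One step up (capped at LR-4; LR-5 is never
   reachable through ancillary features) with at least one malignancy
   feature and none favoring benignity; one step down in the converse
   case; no change when both kinds are present. An LR-3 observation lifted
   to LR-4 here is flagged `upgraded_from_lr3`, which later blocks the
   ancillary-upgrade conditions.
5. **Reader override.** A recorded reader category replaces the engine
   output and is flagged `override_applied`.

Two conventions the published algorithm leaves implicit are fixed here and
tested: size bins are half-open (`<10`, `[10, 20)`, `>=20` mm, so a 20 mm
lesion falls in the large bin), and in the 10–19 mm one-feature cell LR-5
requires washout or threshold growth — capsule alone gives LR-4.
`lirads_table_lookup()` is a literal cell-by-cell transcription of the
table, deliberately sharing no code with the engine; the test suite
compares the two exhaustively over all 2 x 3 x 2^3 combinations.

### Interpretation parameters

Four parameters select the reading; their defaults are the standard v2018
interpretation and each adjustment condition changes exactly one of them.

| parameter | default | meaning |
|---|---|---|
| `washout_def` | `"PVP_ONLY"` | `"PVP_OR_TP"` also accepts transitional-phase hypointensity as washout |
| `washout_requires_aphe` | `FALSE` | `TRUE` disregards washout when effective APHE is absent |
| `aphe_source` | `"ORDINARY"` | `"ORDINARY_OR_SUBTRACTION"` lets a `GLOBAL` subtraction pattern count as nonrim APHE |
| `growth_dialect` | `"V2018"` | `"V2017"` restores the two retired threshold-growth definitions |

Subtraction semantics: a `GLOBAL` subtraction pattern supplies APHE when
the ordinary reading is absent *and* overrides a rim ordinary reading
(the lesion leaves the targetoid gate and re-enters the table); a `RIM`
subtraction pattern never rescues anything. Growth: v2018 threshold growth
is >= 50% within <= 6 months (boundaries inclusive); >= 100% over more
than 6 months and a new >= 10 mm nodule within 24 months are subthreshold
under v2018 but threshold under the v2017 dialect; an unequivocal
below-threshold increase is subthreshold under both.

### Double counting and direction of the conditions

When a modified reading promotes a finding to a major feature, its
ancillary twin is removed for that evaluation (`TP_HYPOINTENSITY` under
`PVP_OR_TP`; `SUBTHRESHOLD_GROWTH` for records grading threshold under
v2017). Counting one finding twice could only inflate upgrades. Removal,
however, can strand an observation whose baseline LR-4 depended on that
ancillary: a sub-20 mm no-APHE lesion upgraded LR-3 to LR-4 by the
transitional-phase ancillary would recompute to LR-3 once the feature
changes role. We treat conditions 3, 5 and 6 as one-directional
relaxations — reading *more* findings must not cost a category — so
`apply_variant()` floors the recomputed ordinal category at the baseline
one. The restriction (condition 4) is symmetric: it can only remove a
feature, and the three overridden LR-5 observations whose override is
annotated washout-dependent are demoted exactly one category, to LR-4.

## The reference cohort

`build_reference_cohort()` reconstructs the 792-observation cohort (508
HCC, 55 non-HCC malignancies, 229 benign) deterministically from feature
strata — groups of identical records — so that every count is auditable and
the whole construction is bit-identical across runs. The constraint
resource (`inst/extdata/cohort_constraints.yaml`) separates:

* **HARD constraints** — the per-rule 2x2 cells and category margins the
  reconstruction must satisfy exactly (all 25 hold);
* **SOFT constraints** — narrative counts. Fifteen hold; four are
  arithmetically incompatible with the hard set (the LR-4/LR-5 split
  118/370 vs the table-derived 117/371; 83 eligible ancillary upgrades vs
  the 91 the cells force; 13 subtraction-driven LR-4 upgrades vs the 12
  compatible with the net cell change once the LR-M re-entry case is
  counted) and are reported as logged deviations by
  `validate_constraints()`.

Cells the published counts do not pin down are filled by a fixed,
documented allocation: the six baseline LR-5 false positives are all
non-HCC malignancies (the plausible mimic class), LR-3 holds 11 HCC / 4
malignant / 48 benign and LR-M 25 HCC / 35 malignant / 13 benign. Three
LR-5 observations lack APHE and cannot arise from the strict table; they
carry reader overrides annotated washout-dependent, and only the
no-washout-without-APHE condition touches them. Every reported statistic
is recomputed from the features through the engine at call time; expected
counts exist only inside the constraint resource.

```{r constraints}
report <- validate_constraints()
attr(report, "hard_ok")
report[!report$pass, c("id", "severity", "expected", "observed")]
```

## The accuracy statistics

All rules are binary, so their ROC has one interior point and the
trapezoidal AUC collapses to `(sensitivity + specificity) / 2`; the test
suite asserts this identity to 1e-12 and also checks the placement-value
(Mann–Whitney, ties counted half) form. Choices that the published
methods leave open, fixed here:

* **Intervals.** Exact Clopper–Pearson for sensitivity, specificity and
  accuracy (this reproduces the published baseline sensitivity bracket to
  one decimal). PPV and NPV use the same exact method on their own
  numerators and denominators; other software may use logit or score
  intervals there, so predictive-value brackets can differ.
* **McNemar.** The exact binomial two-sided form is the default (it
  reproduces the printed 0.250 and 0.008); the asymptotic chi-square form
  is available but not default.
* **DeLong on 0/1 scores.** With massive ties the placement values remain
  valid and match the two-point ROC; the implementation is cross-checked
  against an independent one (pROC) in the tests.
* **Display.** Percentages are rounded half-up to one decimal; p-values
  print to three decimals with `<0.001` / `>0.999` beyond; the JSON
  sidecar keeps full precision. Degenerate tables (a zero denominator)
  flag the metric undefined instead of failing the whole report.

```{r headline}
cohort <- build_reference_cohort()
base <- assign_category(cohort)
dta_metrics(confusion(positivity(base), cohort$diagnosis),
            variant = "BASELINE_LR5")
```

## The simulator

`simulate_cohort()` draws diagnosis classes and then class-conditional
features; defaults are the reference cohort's prevalences (for example,
84% of HCCs show APHE, 85% show portal venous washout, and benign lesions
are log-normal around an 11 mm median). It emulates the feature structure
the rules consume — nothing more: no lesion location, no patient-level
clustering (the design analyses one lesion per patient), no reader
overrides, and feature correlations beyond the built-in implications
(ancillary tokens implying their features) are not modelled. Property
tests on simulated cohorts therefore establish the logical invariants of
the rule system (containment of C2 in C1, directional monotonicity,
idempotence, audit conservation), not the realism of any particular
prevalence. Problem sizes used by the suite — 2,000 observations for the
invariants, 10,000 for parameter recovery, 2,000 replicates for interval
coverage — keep every property estimate stable under the fixed seeds.

## Known limitations

* The reconstruction is count-faithful, not patient-faithful: within a
  stratum records are identical, and any allocation satisfying the hard
  constraints would be equally valid.
* One published AUC (the HCC-specific-ancillary rule, printed 0.886) is
  arithmetically incompatible with its own 2x2 cells, which force 0.882;
  the discrepancy is surfaced by the test suite rather than reconciled.
* Tumor-in-vein and treated lesions are rejected at validation; CT
  criteria, treatment-response categories and inter-reader agreement are
  out of scope.
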