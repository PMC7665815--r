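# Constraint set for the reconstructed 792-observation reference cohort.
# HARD constraints are the table-derived counts the reconstruction must
# satisfy exactly; SOFT constraints are narrative counts, four of which are
# arithmetically incompatible with the hard set and deviate by design.
version: 1
constraints:
  - {id: total_observations, description: "analyzed observations", expected: 792, severity: HARD}
  - {id: hcc_total, description: "HCC reference diagnoses", expected: 508, severity: HARD}
  - {id: non_hcc_malignancy_total, description: "non-HCC malignant diagnoses", expected: 55, severity: HARD}
  - {id: benign_total, description: "benign diagnoses", expected: 229, severity: HARD}
  - {id: baseline_lr1, description: "baseline LR-1 observations", expected: 116, severity: HARD}
  - {id: baseline_lr2, description: "baseline LR-2 observations", expected: 52, severity: HARD}
  - {id: baseline_lr3, description: "baseline LR-3 observations", expected: 63, severity: HARD}
  - {id: baseline_lrm, description: "baseline LR-M observations", expected: 73, severity: HARD}
  - {id: baseline_lr4_or_lr5, description: "baseline LR-4 or LR-5 observations", expected: 488, severity: HARD}
  - {id: baseline_lr5, description: "baseline LR-5 observations", expected: 371, severity: HARD}
  - {id: baseline_lr5_hcc, description: "baseline LR-5 observations that are HCC", expected: 365, severity: HARD}
  - {id: baseline_lr4, description: "baseline LR-4 observations", expected: 117, severity: HARD}
  - {id: baseline_lr4_hcc, description: "baseline LR-4 observations that are HCC", expected: 107, severity: HARD}
  - {id: c1_tp, description: "LR-5 true positives after upgrade via any malignancy ancillary", expected: 448, severity: HARD}
  - {id: c1_tn, description: "true negatives after upgrade via any malignancy ancillary", expected: 270, severity: HARD}
  - {id: c2_tp, description: "LR-5 true positives after upgrade via HCC-specific ancillary", expected: 401, severity: HARD}
  - {id: c2_tn, description: "true negatives after upgrade via HCC-specific ancillary", expected: 277, severity: HARD}
  - {id: c3_tp, description: "LR-5 true positives with subtraction-image APHE", expected: 378, severity: HARD}
  - {id: c3_tn, description: "true negatives with subtraction-image APHE", expected: 278, severity: HARD}
  - {id: c4_tp, description: "LR-5 true positives with washout conditioned on APHE", expected: 362, severity: HARD}
  - {id: c4_tn, description: "true negatives with washout conditioned on APHE", expected: 278, severity: HARD}
  - {id: c5_tp, description: "LR-5 true positives with washout extended to the transitional phase", expected: 384, severity: HARD}
  - {id: c5_tn, description: "true negatives with washout extended to the transitional phase", expected: 275, severity: HARD}
  - {id: c6_tp, description: "LR-5 true positives with v2017 threshold growth", expected: 380, severity: HARD}
  - {id: c6_tn, description: "true negatives with v2017 threshold growth", expected: 278, severity: HARD}
  - {id: narrative_baseline_lr4, description: "narrative count of baseline LR-4 observations (conflicts with the table-derived 117)", expected: 118, severity: SOFT}
  - {id: narrative_baseline_lr5, description: "narrative count of baseline LR-5 observations (conflicts with the table-derived 371)", expected: 370, severity: SOFT}
  - {id: narrative_c1_eligible_lr4, description: "narrative count of LR-4 eligible for ancillary upgrade (table arithmetic implies 91)", expected: 83, severity: SOFT}
  - {id: narrative_c3_lr4_to_lr5, description: "narrative LR-4 to LR-5 moves under subtraction APHE (with the LR-M move, table arithmetic implies 12)", expected: 13, severity: SOFT}
  - {id: hcc_without_aphe, description: "HCCs without APHE on the ordinary arterial phase", expected: 81, severity: SOFT}
  - {id: hcc_without_aphe_with_pvp_washout, description: "no-APHE HCCs showing portal venous washout", expected: 77, severity: SOFT}
  - {id: hcc_without_aphe_with_subtraction_aphe, description: "no-APHE HCCs showing APHE on the subtraction image", expected: 16, severity: SOFT}
  - {id: hcc_without_pvp_washout, description: "HCCs without portal venous washout", expected: 76, severity: SOFT}
  - {id: hcc_tp_hypo_without_washout, description: "of these, transitional-phase hypointense", expected: 39, severity: SOFT}
  - {id: tp_hypo_no_washout_lr4, description: "TP-hypointense washout-free HCCs in baseline LR-4", expected: 20, severity: SOFT}
  - {id: tp_hypo_no_washout_lr5, description: "TP-hypointense washout-free HCCs in baseline LR-5", expected: 16, severity: SOFT}
  - {id: tp_hypo_no_washout_lrm, description: "TP-hypointense washout-free HCCs in baseline LR-M", expected: 3, severity: SOFT}
  - {id: subthreshold_growth_lr345, description: "subthreshold-growth observations among LR-3/4/5", expected: 34, severity: SOFT}
  - {id: subthreshold_growth_hcc, description: "of these, HCC", expected: 30, severity: SOFT}
  - {id: subthreshold_growth_lr4, description: "subthreshold-growth observations in baseline LR-4", expected: 26, severity: SOFT}
  - {id: subthreshold_growth_lr5, description: "subthreshold-growth observations in baseline LR-5", expected: 8, severity: SOFT}
  - {id: c4_lr5_demotions, description: "LR-5 observations demoted when washout requires APHE", expected: 3, severity: SOFT}
  - {id: c5_tp_hcc_lr4_to_lr5, description: "HCC LR-4 observations upgraded by transitional-phase washout", expected: 19, severity: SOFT}
  - {id: c6_lr4_to_lr5, description: "LR-4 observations upgraded by v2017 threshold growth", expected: 15, severity: SOFT}
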