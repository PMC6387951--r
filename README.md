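# plicasym

Interhemispheric microstructural asymmetry analysis of the posterior limb
of the internal capsule (PLIC) for stroke motor-outcome research.

After a middle-cerebral-artery ischemic stroke, degeneration of the
corticospinal tract (CST) shows up as a left-right asymmetry of diffusion
MRI microstructural maps — NODDI orientation dispersion (ODI), DTI scalars
(FA, MD, AD, RD), and DSI-derived GFA — concentrated in the PLIC, the hub
of the tract. `plicasym` is for imaging researchers who want to quantify
that asymmetry from co-registered parameter maps and region labels, and to
ask how well a baseline asymmetry measure predicts upper-extremity
Fugl-Meyer (FM-UE) motor scores at follow-up in a small cohort.

## What it computes

For a subject with contralesional PLIC voxel values *C* and ipsilesional
values *I*:

* **Interhemispheric mean difference**
  ΔPLIC_Mean = C̄ − Ī.
* **Kullback-Leibler divergence asymmetry**
  ΔPLIC_KLD = ½ Σᵢ p_C(i) ln [ p_C(i) / p_I(i) ],
  computed on a shared 10-bin histogram of the two samples, with bin
  probabilities estimated by James-Stein shrinkage toward the uniform
  distribution (λ\* = (1 − Σθ̂²) / ((N−1) Σ(1/B − θ̂ₖ)²), clipped to
  [0, 1]). The KLD registers any distributional change, not just a shift
  of the mean; its natural log is the predictor used downstream.
* **Exhaustive combination validation**: for n = 9 subjects, all
  C(9, 3) = 84 splits into 6 training / 3 test points; an OLS line per
  training set; test-set NRMSE (normalized by the cohort outcome range);
  the best-fit line is the one whose test NRMSE is nearest the mean; the
  reported r² is optimism-adjusted:
  r²_adj = r²_full − mean(r²_train − r²_full).
* **Deviation from control**: paired two-tailed t-tests (control
  left vs right; stroke ipsi- vs contralesional) and Welch two-sample
  tests (stroke ipsilesional vs controls) per CST region and parameter,
  with Holm step-down adjustment within each region × test-kind family.
* **Lesion metrics**: lesion volume (mL), per-region CST lesion load
  (percent overlap with the labels), and Pearson correlations with FM-UE
  outcomes.

Patient scans are not distributable, so the package ships a seeded
synthetic cohort generator (`generate_cohort()`, `generate_label_volume()`,
`generate_lesion_mask()`) that emulates the study design — 9 stroke + 9
control subjects, a per-subject ipsilesional shift δ that linearly drives
the follow-up FM-UE score — making every stage testable end-to-end.

## Worked example

```r
library(plicasym)

cfg    <- cohort_config(seed = 5)          # 9 stroke + 9 control subjects
cohort <- generate_cohort(cfg)
asym   <- roi_asymmetry(cohort$samples)    # PLIC, 10 bins
val    <- validate_outcomes(asym, cohort$subjects)
subset(val, parameter == "ODI" & outcome == "fm_ue_tp2",
       c(predictor, n_splits, r2_full, r2_adjusted, final_nrmse))
#>        predictor n_splits   r2_full r2_adjusted final_nrmse
#> 1     delta_mean       84 0.9622266   0.9613139  0.06744536
#> 8  log_delta_kld       84 0.8977193   0.8858683  0.11861641
```

Each row summarises the 84-split combination validation of one predictor
of follow-up FM-UE: `r2_adjusted` is the optimism-adjusted coefficient of
determination (here ≈0.96 and ≈0.89 — this seeded cohort carries a strong
injected effect) and `final_nrmse` is the NRMSE of the selected best-fit
line over all nine subjects, as a fraction of the outcome range.

The whole pipeline — write the cohort to NIfTI/CSV, read it back, extract
ROI samples, and run every analysis stage — is one call:

```r
res <- run_pipeline(cohort_config(seed = 5), "results_dir")
```

which writes `asymmetry.csv`, `validation.csv`, `group_stats.csv`,
`lesion_stats.csv`, `lesion_correlations.csv` and a `manifest.json` with
content hashes; rerunning with the same config is byte-identical. A thin
command-line wrapper lives at `inst/scripts/plicasym.R`
(`simulate` / `run-all`).

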