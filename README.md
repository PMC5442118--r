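# aarcmr

Multi-parametric cardiac MR quantification of myocardial infarct size (IS)
and area-at-risk (AAR), with a seeded digital phantom cohort for end-to-end
validation.

## The problem

Myocardial salvage — the fraction of the area-at-risk that a cardioprotective
therapy rescues from infarction — requires measuring the AAR in vivo.
T2/T1 mapping infer the AAR from edema, but interventions such as ischemic
preconditioning (IPC) reduce edema itself and make edema-based imaging
underestimate the AAR. Arterial-spin-labeling (ASL) perfusion CMR instead
detects the persistent perfusion deficit inside the AAR, and its
per-animal, self-calibrated threshold should be robust to such interventions.
`aarcmr` implements the full measurement chain for small-animal
ischemia-reperfusion studies:

* **Phantom cohort** — seeded synthetic short-axis hearts (annular LV,
  transmural AAR sector, nested infarct, partial-edema option) with
  simulated multi-echo spin-echo, Look-Locker inversion-recovery (both FAIR
  inversion scopes), LGE acquisitions and histology labels, structured as
  the four study groups (control / IPC / vehicle / CsA).
* **Relaxometry** — pixel-wise bounded least-squares fits:
  `S0·exp(-TE/T2)` for T2, and `A - B·exp(-t/T1*)` with the Look-Locker
  correction `T1 = T1*(B/A - 1)` for T1, including polarity restoration of
  magnitude data and validity screening.
* **ASL perfusion** — blood-pool-input FAIR quantification
  `MBF = 60 (λ / T1_blood) (T1_global / T1_selective − 1)` in ml/g/min, with
  blood T1 measured from the blood-pool ROI.
* **Regional quantification** — normal-ROI k·SD thresholds (T2/T1 above 1 SD,
  perfusion below 1 SD for AAR and 2 SD for infarct, remote + 5 SD for LGE),
  cluster-filtered masks, planimetry, and per-animal IS/LV%, AAR/LV%,
  IS/AAR% by modality.
* **Agreement statistics** — Bland-Altman bias and limits of agreement,
  paired/unpaired t-tests, one-way ANOVA with Bonferroni correction, group
  mean ± SD summaries, and a study runner that writes CSV tables and
  Bland-Altman panels.

## Worked example

```r
library(aarcmr)

cfg <- phantom_config(aar_fraction = 0.643, is_fraction_of_aar = 0.506, seed = 7)
animal <- simulate_animal("control_01", "control", cfg)
maps <- fit_animal(animal)
maps$t2
#> <parameter_map> T2 (ms): 128x128x7; 2324 valid, 0 invalid pixels
#>   5/50/95%: 22.4 / 33.4 / 44.7 ms
maps$perfusion
#> <parameter_map> perfusion (ml/g/min): 128x128x7; 2324 valid, 0 invalid pixels
#>   5/50/95%: 0.23 / 6.24 / 19.9 ml/g/min

metrics <- quantify_animal(animal, maps)
round(metrics[, c("hist_aar_lv_pct", "t2_aar_lv_pct", "asl_aar_lv_pct",
                  "t1_aar_lv_pct", "hist_is_lv_pct", "lge_is_lv_pct")], 1)
#>   hist_aar_lv_pct t2_aar_lv_pct asl_aar_lv_pct t1_aar_lv_pct hist_is_lv_pct lge_is_lv_pct
#> 1            64.3          63.7           64.8          63.9           32.5          32.5
```

This control animal has a true (histology) AAR of 64.3% of the left
ventricle and an infarct of 32.5%; at the default SNR of 20, T2, T1 and
ASL-1SD all recover the AAR within ~1 point and LGE recovers the infarct
exactly. On an IPC-like phantom (`edema_extent_multiplier = 0.85`) the
T2/T1 estimates drop ~9 points below truth while ASL does not move — the
core contrast the package is built to quantify.

A full study runs with one call — in memory
(`run_study(study_config(seed = 1))`) or on disk with NIfTI/JSON/CSV/PNG
outputs (`run_study_dir(study_config(seed = 1), "study/")`), also exposed as
CLI subcommands in `inst/cli/aarcmr.R` (`simulate`, `fit`, `quantify`,
`compare`, `run-study`).

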