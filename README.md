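# datradiomics

Radiomics analysis of longitudinal DAT SPECT for predicting motor outcome
in Parkinson's disease.

In early PD, striatal dopamine-transporter (DAT) binding falls
heterogeneously across the caudate, putamen and ventral striatum. This
package implements a complete, testable pipeline for the question: *do
texture (radiomic) features of longitudinal DAT SPECT improve prediction of
year-4 motor severity (MDS-UPDRS-III) beyond clinical measures and
conventional uptake metrics?* It provides:

* **`phantom_cohort`** — a synthetic striatal phantom generator: six
  mirrored striatal ROIs plus occipital reference and white matter, textured
  laterally-asymmetric uptake blurred to SPECT resolution (6 mm FWHM),
  two timepoints with progression, clinical covariates, and a year-4
  UPDRS-III outcome `y = a0 + a1*UPDRS(y1) + a2*ΔUPDRS + a3*texture +
  a4*decline + ε` in which image texture carries signal beyond the clinical
  variables.
* **`spatial_alignment`** — rigid SPECT-to-MRI registration maximizing
  normalized mutual information `(H(F)+H(M))/H(F,M)` with 7 mm smoothing and
  coarse-to-fine (4 → 2 mm) sampling; striatum-weighted two-stage protocol
  (white matter rescaled to 100, caudate/VS set to 4000, putamen to 1000);
  nearest-neighbour label propagation; more/less-affected side assignment
  from putaminal uptake.
* **`feature_extraction`** — 92 features per ROI per timepoint: 13
  first-order, 22 morphological (17 shape-only), 57 textural
  (GLCM/GLSZM/GLRLM, incl. difference entropy, SZHGE, LZLGE), with the
  conventional quartet SUVmax/SUVmean/SUVpeak/ROI-volume; all from
  occipital-normalized uptake, discretized at 64 gray levels.
* **`outcome_model`** — nested predictor groups (1: non-imaging,
  2: +conventional, 3: +radiomics), zero-variance/dynamic-range/redundancy
  filtering, random forests (bootstrap with ~2/3 unique subjects, min node
  5, mtry = p/3), out-of-bag permutation importance (%IncMSE), leave-one-out
  cross-validated absolute error Δ with paired Wilcoxon group comparison,
  and a pruned exploratory regression tree.
* **`run_experiment()`** — one seeded, reproducible end-to-end experiment
  with YAML config and CSV/JSON/NIfTI artifacts.

## Worked example

```r
library(datradiomics)

cfg <- experiment_config(seed = 5, n_subjects = 8, n_trees = 60,
                         groups = c(2, 3), grid_shape = c(32, 32, 28))
report <- run_experiment(cfg)
print(report)
```

```
Experiment report (seed 5 , n = 8 )
  longitudinal  group2  delta = 15.22 +/- 3.63
  longitudinal  group3  delta = 17.09 +/- 3.01
  baseline_only group2  delta = 16.72 +/- 3.50
  baseline_only group3  delta = 15.67 +/- 2.85
  group2_vs_group3: p = 0.2936
```

Each `delta` is the leave-one-out mean absolute error (UPDRS-III points) of
that predictor group; group 3 adds the radiomic features to group 2's
clinical + conventional predictors. At this toy size (n = 8) the radiomic
group shows no reliable gain — eight subjects cannot support ~1600
predictors. At the package's study scale (n = 64, 500 trees) the
longitudinal radiomic group beats the conventional group systematically
(in 10/10 outcome-noise replicates in the packaged tests), while the
null-imaging configuration (`imaging_signal = FALSE`) shows no group-3
advantage.

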