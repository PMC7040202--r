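# radsig

Radiomic signature modelling for progression-free survival on CT volumes:
feature extraction, redundancy-aware feature selection, Cox signature
fitting, and survival evaluation — plus a synthetic-phantom simulator so the
whole chain can be exercised and validated without patient data.

## What it does

- **I/O** — NIfTI-1 (`.nii`, `.nii.gz`) and NRRD (raw encoding) volumes,
  clinical CSV tables with schema validation, feature-table CSVs that
  round-trip at full double precision, and JSON artifacts for every pipeline
  stage.
- **Feature extraction** — 481 features per image/mask pair: 13 shape
  descriptors and, on the original image plus 8 stationary coif1 wavelet
  sub-bands, 16 first-order statistics, 24 gray-level co-occurrence (GLCM)
  features and 12 gray-level run-length (GLRLM) features. Volumes are
  resampled to 1 mm isotropic, intensities discretized to 32 equal-width
  levels inside the VOI, and texture features averaged over the 13 unique 3D
  directions.
- **Synthetic phantoms** — ellipsoidal tumors with a correlated, optionally
  skewed Gaussian texture over a noisy background, and cohorts whose
  progression times follow an exponential proportional-hazards model linked
  to the texture parameters (or to nothing, for null cohorts).
- **Selection** — training-cohort z-score normalization, Pearson redundancy
  pruning (|r| > 0.8), LASSO-penalized Cox regression with 10-fold
  cross-validated penalty choice, an events-per-variable guard, and a
  stability analysis over repeated random cohort splits.
- **Signature + evaluation** — multivariate Cox signature with a
  training-median cutoff, Kaplan–Meier curves, G-rho (rho = 1) log-rank
  test, Harrell's C-index with bootstrap CI, time-dependent AUC at 6 months
  (IPCW), univariate hazard-ratio tables, clinical/combined Cox models and
  baseline chi-square cohort comparisons. The fixed published scoring rule
  is available as `published_signature()`.

## Quick start

```r
library(radsig)

# one synthetic patient
ph <- generate_phantom(phantom_params(), seed = 1)
features <- extract_all(ph$img, ph$mask)
length(features)  # 481

# a full cohort study from a config
cfg <- pipeline_config(list(
  paths = list(cohort_dir = "cohort", output_dir = "out"),
  simulation = list(n_patients = 63, seed = 1),
  extraction = list(wavelet = TRUE)))
pipeline_run_all(cfg)
```

Artifacts land in `out/`: `features.csv`, `selection.json`,
`signature.json`, `evaluation.json`, per-cohort Kaplan–Meier and ROC curve
CSVs, a forest-plot table and a `pipeline.log`.

From the shell:

```sh
Rscript inst/cli/radsig.R config.yaml all
```

Exit codes: 0 success, 2 usage/config error, 3 runtime failure.

## Real data

`read_image()` / `read_mask()` accept NIfTI or NRRD pairs on a common grid;
`read_clinical()` expects columns `patient_id, sex, age_years, smoking,
pfs_days, event` (and optionally `cohort_label`). Point
`paths$cohort_dir` at a directory with `images/<id>.nrrd`,
`masks/<id>.nrrd` and `clinical.csv`, then run the `extract` stage onward.

## Validation

`tests/testthat/` contains the unit and property suites (brute-force texture
oracles, closed-form survival fixtures, calibration simulations) and
`test-acceptance.R` with the release criteria. `scripts/acceptance.R` writes
a machine-readable summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

See the methods vignette (`vignettes/radiomic-signature-methods.Rmd`) for
the numerical conventions and their measured accuracy.
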