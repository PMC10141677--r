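# bonetex

Texture-based bone age estimation from wrist MRI.

Skeletal ("bone") age measures a child's biological maturation and is
routinely read from hand radiographs. `bonetex` implements a
radiation-free alternative on coronal wrist MRI for radiologists and
image-analysis researchers: the distal radius is described by radiomic
texture features of two regions of interest — the trabecular **bone**
and the cartilaginous **growth region**, whose bright, water-rich band
narrows and calcifies through adolescence — and age is regressed
directly from texture.

The pipeline, end to end:

* **I/O and ROIs** — 12-bit single-frame DICOM or 8-bit PNG renditions
  (512×512, pixel spacing 0.2539–0.3516 mm); rectangular ROIs in pixel
  or metric (mm) units, so the physical patch is constant across
  heterogeneous spacings.
* **±3σ normalization** — each region I(x, y) is linearly remapped so
  that μ − 3σ ↦ 0 and μ + 3σ ↦ L (L = 255 or 4095), clamped and
  rounded:  N(x, y) = L · (I − (μ − 3σ)) / 6σ.
* **307 texture features** per region: 9 histogram, 220 gray-level
  co-occurrence (11 Haralick statistics × 4 directions × distances
  1–5), 20 run-length (5 Galloway statistics × 4 directions), 5
  gradient, 5 autoregressive, 16 Haar wavelet energies (4 scales × 4
  subbands), 24 Gabor (4 orientations × 6 envelopes), 8
  orientation-histogram bins.
* **Regression** — per fold: Spearman |ρ| top-15 selection → PCA to 3
  components → two-hidden-layer perceptron (10 + 10 ReLU units, linear
  output); evaluated by leave-one-out cross-validation with pooled
  R², RMSE, MSE and MAE.
* **Synthetic cohort generator** — the study's patient data are
  private, so `generate_cohort()` emulates the cohort (30 patients, 55
  images, ages 9–17, T1/T2 contrasts, 12-bit masters with 8-bit
  renditions) with a controlled, monotone age→texture effect, making
  every stage testable.

## Worked example

Simulate the default cohort, extract the bone-region descriptor from
the 12-bit T1 masters, and run the leave-one-out evaluation:

```r
library(bonetex)

cohort <- generate_cohort(cohort_spec(seed = 42))
bone   <- cohort_to_feature_table(cohort, "bone", "T1", 12L)
report <- loo_evaluate(bone, pipeline_config(seed = 42))
report
#> <loo_report> n=55  R2=0.9466  RMSE=0.5684  MSE=0.3231  MAE=0.4358  (k15-pc3-h10x10-e600-lr0.02-l20.03-imagefold, seed 42)

head(report$predictions, 3)
#>   row patient_id age_years predicted
#> 1   1       P001         9  8.925905
#> 2   2       P001         9  9.043566
#> 3   3       P002         9  8.977622
```

Each of the 55 images was predicted by a model trained on the other 54
(selection, PCA and network re-fitted per fold): the pooled R² of 0.95
says the texture of the synthetic trabecular patch explains nearly all
age variance at full effect strength, and the MAE of 0.44 years is the
average absolute age error. With shuffled age labels the same pipeline
collapses to R² ≤ 0 — the signal is in the texture, not the machinery.

The numbered scripts under `analysis/` run the full workflow on disk:
`01_simulate.R` (write DICOM + PNG cohort with manifest and ROI
config), `02_extract_features.R` (one feature CSV per region × contrast
× encoding), `03_loo_evaluate.R` (per-variant LOO reports and a summary
`results/metrics.csv`), `04_dose_response.R` (pooled R² versus effect
strength).

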