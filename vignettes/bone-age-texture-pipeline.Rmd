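---
title: "Texture-based bone age estimation from wrist MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based bone age estimation from wrist MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonetex)
```

## The problem

Skeletal ("bone") age quantifies a child's biological maturation and can
differ from chronological age under endocrine, nutritional or other
influences. It is conventionally read from hand radiographs; MRI offers a
radiation-free alternative. The premise of this package is that the
*texture* of the distal radius in coronal wrist MRI — the trabecular
pattern of the bone and the bright band of the cartilaginous growth
plate — carries enough maturation signal to regress age directly from
texture descriptors. In adolescents the growth plate is a thin,
water-rich zone that appears bright (especially on T2-weighted images)
and progressively narrows and calcifies; marrow composition and
trabecular structure also evolve with age.

The pipeline has four stages, each a module of this package:

1. **Region extraction** (`read_scan()`, `roi_spec()`, `extract_region()`):
   scans arrive as 12-bit single-frame DICOM or 8-bit PNG renditions,
   512x512, pixel spacing 0.2539–0.3516 mm. Rectangular ROIs are placed
   on the trabecular bone and on the growth region. ROIs may be sized in
   pixels or millimetres; metric sizing divides by the pixel spacing and
   rounds half away from zero, keeping the physical patch constant in a
   cohort with heterogeneous spacings.
2. **Intensity normalization** (`normalize_3sigma()`): each region is
   remapped so that \(\mu - 3\sigma \mapsto 0\) and
   \(\mu + 3\sigma \mapsto L\) (\(L = 255\) or \(4095\)), with clamping
   and integer rounding.
3. **Texture description** (`extract_all()`): 307 named features per
   region (details below).
4. **Age regression** (`loo_evaluate()`): per-fold Spearman top-15
   selection, PCA to 3 components, and a two-hidden-layer perceptron,
   evaluated by leave-one-out (LOO) cross-validation with pooled
   \(R^2\), RMSE, MSE and MAE.

Because the underlying patient data are private, the package ships a
synthetic cohort generator (`generate_cohort()`) that emulates the
cohort's geometry and a controlled, monotone age-to-texture
relationship, so every stage is testable end to end.

## The texture descriptor

The 307 features comprise eight families:

| family | count | contents |
|---|---|---|
| histogram | 9 | mean, variance, skewness, kurtosis, percentiles 1/10/50/90/99 |
| co-occurrence | 220 | 11 Haralick statistics x 4 directions x distances 1–5 |
| run-length | 20 | 5 Galloway statistics x 4 directions |
| gradient | 5 | moments + nonzero fraction of a 3x3 high-pass magnitude map |
| autoregressive | 5 | 4 causal neighbour weights + residual RMS |
| Haar energy | 16 | mean squared coefficient, 4 dyadic scales x 4 subbands |
| Gabor | 24 | mean response magnitude, 4 orientations x 6 envelope sizes |
| orientation histogram | 8 | magnitude-weighted 8-bin gradient orientation histogram |

Design choices where the method family admits variants (each fixed and
covered by tests):

* **Quantization.** Co-occurrence and run-length features use uniform
  re-binning of \([0, L]\) into \(G = 64\) levels, a common default in
  MR texture analysis software that bounds the co-occurrence matrix at
  64x64 for both bit depths. `feature_config(levels = )` exposes it.
* **Directions** are the (row, col) offsets \((0,d)\), \((d,d)\),
  \((d,0)\), \((d,-d)\); co-occurrence matrices are symmetrized, so they
  are exactly doubly stochastic up to normalization and sum to 1.
* **Haralick statistics** use 1-based gray-level indices, natural
  logarithms, the \(0\log 0 = 0\) convention, correlation defined as 0
  for degenerate matrices, and sum variance taken about the sum average.
* **Gradient mask** is the 4-neighbour Laplacian; its absolute response
  is the magnitude map. Any 3x3 zero-DC high-pass would serve; the
  Laplacian makes the DC-invariance property exact.
* **Autoregressive model**: the region is mean-centred, then each pixel
  is regressed on its left, upper-left, upper and upper-right
  neighbours by least squares (minimum-norm solution when
  rank-deficient, so constant regions give \(\sigma_{AR} = 0\)).
* **Haar energies** crop the region (top-left) to the largest size
  divisible by \(2^4\) before a 4-scale orthonormal transform — no
  padding, so subband energies obey Parseval exactly.
* **Gabor kernels** have isotropic Gaussian envelope \(\sigma = s/2\),
  carrier wavelength \(\lambda = s\), support half-width \(s\), a
  DC-corrected even part, and unit-\(L^1\) envelope normalization so
  response magnitudes are comparable across envelope sizes (without
  this, larger envelopes dominate at every frequency and scale
  selectivity is lost).
* **Kurtosis** is excess kurtosis (Gaussian = 0); skewness/kurtosis of
  constant data are defined as 0. Percentiles are type-7 quantiles.
* **Normalization before every family.** Whether gradient-type features
  should see raw or normalized intensities is ambiguous in general;
  here normalization precedes all families, which matches the pipeline
  description order and makes the descriptor invariant to affine
  intensity changes of the acquisition.

The one normalization subtlety: the published clamp is stated for the
8-bit range. For 12-bit input this package generalizes the ceiling to
4095 so the 12-bit dynamic range — the best-performing representation —
is preserved; `normalize_3sigma(ceiling_override = 255)` restores the
literal 8-bit clamp. \(\sigma\) is the population standard deviation; a
constant region maps to mid-gray \(L/2\) rather than dividing by zero.

## The regression pipeline

With only a few dozen samples and 307 features, selection and reduction
must happen *inside* each cross-validation fold or the held-out sample
leaks into the model. `loo_evaluate()` therefore re-runs, per fold:

1. Spearman ranking of all features against age on the training rows;
   the top 15 by \(|\rho|\) are kept (ties broken by schema order; sign
   is irrelevant to a nonlinear regressor).
2. PCA on the selected features (centred, unit-variance scaled by
   training statistics); the first 3 components are kept.
3. A perceptron with two hidden layers of 10 rectified-linear units and
   a linear output, trained by full-batch Adam (learning rate 0.02, 600
   steps, L2 weight decay 0.03) on inputs and target standardized by
   training-fold statistics.

The weight decay deserves a comment: with ~160 parameters and ~54
training samples the unregularized network interpolates its training
folds and generalizes poorly; a small ridge penalty (together with a
fixed, modest step budget) stabilizes the LOO predictions without
affecting the network's capacity for the smooth, low-dimensional
age-score relationship. All three constants are deliberate, documented
defaults of `pipeline_config()`, not tuned per dataset.

Every fold draws its weight initialization from `seed + fold_index`, so
a report is reproducible from one top-level seed. \(R^2\) is computed on
the pooled LOO predictions about the overall mean age, matching the
single-\(R^2\)-per-dataset reporting convention. The fold unit is one
image; `pipeline_config(group_folds = TRUE)` switches to
leave-one-patient-out for cohorts where patients contribute several
images (the stricter protocol when patient-level effects dominate).

## The synthetic cohort

`generate_cohort()` emulates the study conditions: 30 patients, up to 3
usable images each (55 in total), integer ages 9–17 drawn with weights
giving mean ≈ 12.4 and median 12, pixel spacings
\{0.2539, 0.2734, 0.293, 0.3125, 0.3516\} mm with 0.293 mm most
frequent, 12-bit masters in T1 and T2 contrast, and 8-bit renditions by
per-image min-max rescaling.

Each scan is built from three structural fields: a smoothed-noise marrow
background, a trabecular slab of correlated noise, and a horizontal
growth band with a Gaussian cross-profile. The age effect (scaled
globally by `effect_strength`) follows the radiological picture:

* band width 3.5 mm at age 9, shrinking 0.25 mm/year;
* band brightness 1400 (12-bit units) at age 9, dropping 120/year;
* calcified foci inside the band: dark speckle whose area fraction grows
  9 %/year from zero — this is what shape-sensitive histogram features
  see after normalization has removed absolute brightness;
* trabecular mean intensity falling 90/year, contrast rising 30/year,
  correlation length falling 0.15 px/year (younger = coarser pattern).

Patients carry age-independent jitters (e.g. SD 30 on band brightness,
0.12 mm on width) so that at `effect_strength = 0` the texture is
statistically independent of age. Effect sizes are free parameters of
the emulation — the source cohort is not available to calibrate against
— and were chosen once so that the full pipeline recovers the age signal
at full effect (pooled LOO \(R^2 \ge 0.8\) on the bone region) and
collapses under label shuffling, which is exactly what they are for.

What the generator does **not** emulate: anatomy (no carpal bones, no
curved physis), MR physics (coil profiles, chemical shift, motion),
inter-scanner variation, and ROI placement error. Passing recovery tests
therefore demonstrate that the pipeline's machinery — normalization,
descriptor, per-fold selection/reduction, regressor, LOO bookkeeping —
extracts a monotone texture-age relationship when one exists; they do
not validate clinical accuracy on real data.

## Numerical conventions and degenerate inputs

* Rounding is half-away-from-zero everywhere (metric ROI resolution,
  normalization, 8-bit rendition), for platform determinism.
* Constant regions: all 307 features are finite by convention
  (skewness/kurtosis 0, \(\sigma_{AR} = 0\), empty orientation
  histogram all zeros, mid-gray normalization).
* A region must be at least 24x24 (largest Gabor envelope) and 16x16
  (4 wavelet scales) for the full descriptor; smaller regions fail with
  the family named in the error.
* PCA fails with a rank error if the training rows span fewer
  non-degenerate directions than requested components; constant
  features are given unit scale rather than dividing by zero.
* DICOM support is deliberately narrow: uncompressed little-endian,
  single-frame, grayscale, with rescale slope/intercept applied and
  rounded if present. PNG carries no pixel spacing, so metric ROIs on
  PNG require an explicit spacing in the manifest.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
cohort sizes of the emulated study (55 bone / 30 growth samples); the
dose-response sweep uses 30-image cohorts at three seeds per effect
level, which is ample to see the monotone trend. The test suite uses
smaller cohorts (8–20 images) for structural checks and the full 55 for
the recovery property.

## Known limitations

* The perceptron is a from-scratch implementation specified by its
  training constants; it reproduces the *class* of model named by the
  study (a bilayered fully-connected ReLU regressor), not any toolbox's
  exact iterate sequence.
* Texture features are single-ROI; no per-pixel feature maps.
* The published per-dataset error tables stem from private patient data
  and are not reproducible here; the package's own results quantify the
  synthetic emulation only.
* Ages are integer labels; the months-resolution variant of the problem
  is out of scope.
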