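---
title: "Longitudinal DCE-MRI delta-radiomics: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal DCE-MRI delta-radiomics: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In triple-negative breast cancer (TNBC), roughly half of patients reach a
pathologic complete response (pCR) after neoadjuvant systemic therapy.
Identifying likely non-responders early — after two or four chemotherapy
cycles rather than at surgery — would let oncologists redirect therapy and
spare patients ineffective, toxic treatment. Early-phase DCE-MRI
subtraction images carry that information: responding tumors de-enhance
and shrink, and the texture of both the tumor and its microenvironment
changes.

`deltaradiomics` implements a complete, testable version of this
analysis: region-of-interest geometry, a 310-feature radiomic extraction,
longitudinal delta features, univariate dual-cohort AUC screening,
elastic-net logistic modelling, and interreader reliability — plus a
synthetic cohort generator, because patient imaging of this kind cannot
be redistributed. Every stage is exercised end to end on generated data.

## The pipeline

For each subject the input is an early-phase DCE subtraction volume and a
binary tumor mask at three time points: baseline (BL), after two cycles
(C2), after four cycles (C4). When no enhancing tumor remains at C2/C4,
the mask is a segmented *tumor bed*.

1. **Peritumoral ring.** The tumor mask is expanded outward by a fixed
   physical thickness (default 10 mm) using a spacing-aware exact
   Euclidean distance transform; the ring is the set of voxels with
   distance in `(0, 10]` mm. The upper bound is closed, so a voxel at
   exactly 10 mm belongs to the ring. No breast/air masking is applied —
   the expansion is purely geometric, which matches the stated procedure
   of the source analysis but means rings near the skin include
   background voxels; we document this as a limitation rather than guess
   at an unstated masking step.
2. **Features.** 310 per ROI per time point: 10 first-order statistics of
   the raw intensities (min; max; mean; SD; 1st/5th/95th/99th
   percentiles; skewness; kurtosis) and 300 GLCM features — for each of
   five gray-level quantizations (8, 16, 32, 64, 256), 20 co-occurrence
   scalars aggregated over the 13 canonical 3D directions by mean, range
   and angular variance (population variance across directions).
3. **Deltas.** Absolute (`AD = late − early`) and relative
   (`RD = (late − early)/|early|`) differences for the pairs C2BL, C4BL,
   C4C2, giving 2790 columns per region, 5580 per subject, named
   `<Region>_DCE_<Block>_<FO|GLCM>_<Name>`
   (e.g. `Peritumoral_DCE_RD-C4BL_FO_Percentile.95`).
4. **Screen.** Stratified 2:1 train/test split; per feature, training and
   testing AUC with DeLong 95% CIs and a training Wilcoxon rank-sum
   p-value; selection requires AUC ≥ 0.70 in *both* cohorts (inclusive)
   and p < 0.05.
5. **Models.** Elastic-net logistic regression over declared feature
   blocks, tuned by mean 5-fold cross-validated AUC over a grid of
   mixing parameter × penalty path, evaluated once on the held-out test
   set; models are flagged at dual-cohort AUC ≥ 0.75. The default suite
   is the 20 published model definitions parsed from their names.
6. **Reliability.** Per-feature Pearson correlation and Wilcoxon
   signed-rank test between readers, and an
   interreader-to-cohort variance ratio.

## Numerical conventions (all recorded in output metadata)

Several conventions are not fixed by the source description; the package
chooses standard ones and exposes them:

* **Quantization**: equal-width bins on the in-ROI `[min, max]`; the
  maximum maps to the top level; a constant ROI maps to level 1. GLCMs
  are accumulated in 3D (volumetric ROIs), symmetrically, both pair ends
  in-mask, then normalized.
* **Direction set**: the 13 unique offsets at Chebyshev distance 1.
  This set is closed under 90° axis rotations, which makes the
  mean/range/angular-variance aggregates rotation invariant on isotropic
  grids (verified to 1e-10 in the tests).
* **The 20 GLCM scalars**: the published list contains a duplicated
  entry ("cluster prominence" twice) and so names only 19 distinct
  scalars. We substitute GLCM **entropy** for the duplicate — it is the
  member of the classic Haralick/Soh/Clausi 20-scalar family otherwise
  absent. This is a package decision, not a recovered fact.
* **Entropies** use base-2 logarithms with `0·log 0 = 0`; correlation and
  IMC1 are missing for degenerate (constant) matrices.
* **First-order**: percentiles by linear interpolation (type 7), SD with
  `n − 1`, adjusted Fisher–Pearson skewness, Pearson kurtosis
  (normal = 3). Singleton ROIs leave SD/skewness/kurtosis missing.
* **RD definition**: the denominator is `|early|` so the sign of RD
  always matches the direction of change, including for negative-valued
  features such as cluster shade; RD is a fraction, not a percentage.
  AUC-based results are invariant to both choices (monotone transforms).
* **Missing values** propagate by pairwise deletion: empty ROIs yield
  310 missing features, deltas of missing are missing, the screen drops
  missing scores per feature, and models drop incomplete subjects per
  model.
* **Orientation**: univariate AUCs are reported ≥ 0.5 with the direction
  determined on the *training* cohort and applied unchanged to the
  testing cohort (orienting each cohort separately would bias the dual
  test upward). Model AUCs are unoriented.
* **Split arithmetic**: per class, round-half-up of 2n/3 to training —
  with 78 pCR / 85 non-pCR this reproduces the published 52/57 training
  and 26/28 testing class counts exactly.
* **Elastic net**: both hyperparameters are tuned (α over 0.1–1.0 in
  steps of 0.1, λ over the glmnet path), because the source names only
  "the tuning parameter"; folds are stratified and seeded; ties in mean
  CV AUC break toward the strongest penalty (largest λ, then largest α)
  for a parsimonious, deterministic choice; features are standardized
  with training-set statistics only. None of these settings is claimed
  to equal the original analysis — they are documented alternatives.

## The synthetic cohort: what it emulates, and what a green test means

The patient data behind the original analysis are not shareable, so the
generator states a synthetic world with the structure the analysis
assumes, and the defaults are fixed once:

* 78 pCR / 85 non-pCR subjects (the published cohort size);
* axis-aligned ellipsoidal tumors with BL semi-axes drawn from 6–12 mm
  (lesion diameters of roughly 1.2–2.4 cm, the size range of the
  published example lesions), on ~1 × 1 × 3 mm grids (typical in-plane vs
  slice resolution);
* per-time-point decay factors applied to both semi-axes and mean
  enhancement: `(1, 0.55, 0.15)` for pCR and `(1, 0.9, 0.75)` for
  non-pCR — responders de-enhance strongly by C4, non-responders mildly;
* a low-enhancement shell (30% of tumor enhancement) around the tumor,
  standing in for the enhancing microenvironment;
* multiplicative spatial texture from Gaussian-smoothed white noise
  (correlation length 3 mm, coefficient of variation 0.3 — chosen so
  GLCM features are non-degenerate) plus additive Gaussian noise
  (SD 5 at BL tumor enhancement 100, i.e. SNR ≈ 20);
* an empty enhancing region at C2/C4 is replaced by the previous time
  point's mask flagged as tumor bed, which keeps extraction defined at
  every time point;
* simulated second-reader and repeat segmentations from bounded smooth
  boundary jitter (default 1 mm; repeats at half that), with the
  symmetric difference guaranteed to lie within the stated magnitude of
  the original boundary.

The generator does **not** model pharmacokinetics, acquisition physics,
breast anatomy, registration error, or inter-scanner variation. A green
parameter-recovery test therefore establishes that the *pipeline*
recovers planted longitudinal effects and stays calibrated under the
null — it does not, and cannot, reproduce the published patient-level
AUCs, which require the original images.

Intrareader repeat segmentations are not described explicitly in the
source; the generator provides them (at half the interreader jitter) so
the variance-ratio analysis is exercisable, and this is documented as a
stand-in.

## The variance ratio

The source summarizes interreader agreement by a "ratio of interreader
to intrareader variance" without a formula. We implement a
paired-difference variance-components estimator: with reader-1 values
$x$, reader-1 repeats $x'$ and reader-2 values $y$,

$$\hat\sigma^2_\text{intra} = \tfrac12\,\overline{(x - x')^2},\qquad
  \hat\sigma^2_\text{inter} = \max\!\bigl(0,\;
  \tfrac12\,\overline{(x - y)^2} - \hat\sigma^2_\text{intra}\bigr),$$

reported as $\hat\sigma^2_\text{inter}$ normalized by the cohort variance
of $x$ (with 0/0 defined as 0). This reproduces the qualitative behaviour
reported for the original cohort — ratios near zero, median exactly zero
when readers frequently agree — and is documented as an interpretation,
not a recovered definition.

## Null calibration and correlated features

Radiomic features are strongly correlated (the five gray levels of one
scalar, percentile families, AD/RD of the same feature), so the fraction
of null features with p < 0.05 has the binomial mean 0.05 but a much
larger variance than independent-feature binomial sampling would give.
The calibration test therefore uses a generous 3σ band computed for an
effective number of independent feature clusters of order tens, rather
than the literal 5580-feature binomial interval, and additionally checks
that dual-cohort selections are rare and null model test AUCs stay in
[0.35, 0.65].

## Performance notes

The distance transform (exact, anisotropic, Felzenszwalb–Huttenlocher)
and GLCM pair counting are implemented in C++; everything above them is
vectorized R. Feature extraction crops to the mask bounding box (valid
because both ends of a counted pair must lie in the mask) and evaluates
the co-occurrence scalars on the nonzero GLCM entries only. A full
163-subject cohort at test scale (24³ voxels) extracts in about a
minute on one CPU.

## Known limitations

* The peritumoral ring includes background/air voxels near the breast
  surface (no anatomical masking).
* GLCM features are computed in 3D; a per-slice 2D variant is not
  offered.
* No shape, wavelet, run-length or size-zone feature families — the
  feature set is exactly the 310 described above.
* The published patient-level AUC tables are not reproducible without
  the original data; the acceptance suite targets structural and
  parameter-recovery claims instead.
* No imputation: subjects with missing design values are dropped per
  model, which with aggressive simulated shrinkage (near-empty C4 masks)
  can reduce the effective training set.
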