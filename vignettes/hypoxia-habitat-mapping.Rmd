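---
title: "Mapping hypoxic tumor habitats from multiparametric MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping hypoxic tumor habitats from multiparametric MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatmap)
```

## The problem

Tumor hypoxia is heterogeneously distributed in space, broadly
therapy-resistant, and the condition under which hypoxia-activated prodrugs
(HAPs) such as evofosfamide (TH-302) become cytotoxic. The standard readout
of hypoxia — pimonidazole (PIMO) immunohistochemistry — requires excising the
tissue, so it cannot stratify subjects before therapy or monitor them during
it. `habitatmap` implements a noninvasive alternative: learn the mapping
from multiparametric MRI (mpMRI) to the PIMO label on co-registered
MRI/histology pairs, then predict a per-pixel *hypoxia probability* and a
per-slice *hypoxia fraction* from MRI alone. The per-slice fraction supports
responder stratification (AUROC, Youden cutoff) and longitudinal monitoring.

The package covers five processing stages, each usable on its own:

1. **DCE parametric maps** (`compute_auc`, `compute_slope`, `compute_ttm`),
2. **PIMO masking** of stain images by per-slice Otsu thresholds
   (`otsu_threshold`, `binarize_stain`),
3. **Co-registration**: polygon rasterization, 4-landmark affine fit,
   area-fraction downsampling, Dice QC
   (`rasterize_mask`, `fit_affine`, `resample_to_mri`, `dice`, `qc_gate`),
4. **Patch CNN** (`extract_patches`, `train_hypoxia_cnn`, `predict_map`,
   `select_cutoff`),
5. **Evaluation statistics** (`pearson_by_cohort`, `auroc`, `youden_cutoff`,
   `longitudinal_table`).

A synthetic phantom generator (`phantom_spec`, `generate_cohort`) emulates
the paired-acquisition study design with a *known* MR-to-hypoxia link so
that every stage can be verified against ground truth.

## Semi-quantitative DCE maps

The dynamic contrast-enhanced (DCE) series is a T1-weighted signal
$S(t)$ sampled at each pixel over repetitions roughly 70 s apart, with
contrast injected after the first (baseline) repetition. Three
semi-quantitative summaries are computed per pixel:

* **AUC** $= \sum_t S(t)$ — the plain sum over the *entire* dynamic curve,
  not just initial uptake, so slowly enhancing (possibly hypoxic) regions
  contribute. A trapezoidal variant weighted by the sampling interval is
  available behind `method = "trapezoid"` but is off by default.
* **slope** $= \Delta S_{T1} / \Delta t$, taken from baseline to the maximum
  enhancement; a peak at baseline (flat pixel) gives slope 0 by convention.
* **TTM** — the time of maximum enhancement, measured from the baseline
  acquisition, ties broken toward the earliest repetition.

Acquisition timing always comes from the series metadata (`times`,
`baseline_index`), never from constants. `NA`/`NaN` samples propagate to
the output maps with a single warning rather than being imputed, so
degraded pixels stay visibly degraded.

## PIMO-positive masks

Stain images arrive on an 8-bit stain-intensity scale — 0 meaning no
staining (white) and 255 maximum staining (black). Each slice gets its own
Otsu threshold: the level maximizing between-class variance of the 256-bin
histogram, computed over tissue pixels only (background white space would
otherwise bias the histogram; the tissue restriction is this package's
choice). `binarize_stain` marks tissue pixels at or **at-or-above** the
threshold as positive — the tie side is stated once here and tested. A
cohort-wide global threshold (e.g. 92 for one tumor model, 86 for another)
can be passed through the same `binarize_stain` path for sensitivity
analyses; `per_tumor_summary` averages slice fractions into one value per
tumor.

## Co-registration

Vendor mask files store positive regions as ordered polygon lists. Each
polygon's boundary is drawn with Bresenham's integer line algorithm and its
interior filled by an even-odd scanline pass; polygons are applied in order,
each one *toggling* (XOR) the area it covers. Toggling reproduces the
positive/hole/re-fill drawing-order semantics, is order-independent, and
coincides with even-odd parity at any nesting depth — the convention we
adopt for nesting deeper than two levels, where pure painter's-order
descriptions become ambiguous. The inverse operation `polygonize` traces
component and hole contours (Moore neighbour tracing) and then
self-verifies: any residual pixel difference is toggled by a degenerate
single-pixel polygon, so `rasterize_mask(polygonize(x))` is the identity *by
construction*, not merely in expectation.

Histology and MRI frames are related by a 6-parameter planar affine
estimated from 4 manually placed landmark pairs by linear least squares
(8 equations, 6 unknowns; the residual RMS is reported and exact recovery
on noise-free landmarks is part of the test suite). RANSAC would be
meaningless with 4 points and is deliberately absent. Transformed masks are
brought onto the MRI grid by **area-fraction averaging**: every positive
histology pixel is mapped through the affine and lands in an MRI pixel,
which accumulates `1/scale^2`. The result is a continuous PIMO fraction map
in $[0,1]$ — exactly the quantity the patch labels average — rather than a
nearest-neighbour binary mask. Registration quality is scored with the Dice
similarity coefficient
$\mathrm{DSC} = 2|M \cap H| / (|M| + |H|)$ between the MRI tumor outline
and the transformed tissue outline, and `qc_gate` keeps slices at or above
the cohort mean DSC (equivalently an explicit score such as 0.92). Slices
with broken or missing tissue are expected to be excluded upstream by the
analyst; the gate only enforces the similarity rule.

Coordinates are 0-based `(row, col)` with pixel centers at integers in all
polygon/landmark interfaces, matching the on-disk JSON/CSV schemas.

## The patch classifier

For every pixel inside the tumor mask, a 15×15 window cut from the five
co-located MR channels — in fixed order T2\* map, T2W, slope, TTM, AUC —
forms one training patch (reflection padding at image edges, so rim pixels
are not lost). The patch label is the **binarized window mean** of the PIMO
fraction map: 1 when the mean reaches `label_cut = 0.5`. The 0.5 default is
our choice (exposed in the API) since only "binarized average" is specified
by the underlying design. Channels are z-scored per channel with statistics
pooled over all training patches; per-slice or per-patch normalization
would leak slice composition into the features, so it is not the default.

The classifier is a compact ResNet-18: a 3×3 stem (no 7×7/max-pool — the
input is only 15×15), four stages of two basic residual blocks with
projection shortcuts at each stride-2 transition, global average pooling
and a 2-way softmax head. "Small number of filters" is realized as
`base_filters = 8` with stage widths 8/16/32/64 — enough capacity for a
logistic link while trainable on one CPU. The 2-way softmax over one-hot
labels is retained (mathematically equivalent to a single sigmoid) to
mirror the described architecture. Training uses binary cross entropy,
Adam at an initial learning rate of 1e-4 decayed by 0.2 whenever the
validation loss has not improved for 10 epochs, and
shift/flip/rotation/zoom augmentation — all of which permute or resample
window content around the same center and therefore preserve labels.
Best-validation weights (including batch-norm running statistics) are
restored at the end. Epoch counts and batch size are not specified by the
underlying design; defaults (`max_epochs = 30`, `batch_size = 128`) are
engineering choices in `train_config`. All conv/batch-norm kernels are
compiled (im2col + BLAS GEMM); gradients are verified against numerical
differentiation in the test suite.

Prediction is blind: `predict_map` consumes MR channels only, checks the
channel order against the model, and reconstructs the probability map from
patch-center coordinates. The binarization cutoff is *not* 0.5 by fiat: for
each training sample `select_cutoff` scans a 0.01-step grid for the cutoff
maximizing DSC against the binary PIMO mask (ties toward the lowest value)
and deploys the mean of the per-sample optima.

## Evaluation and stratification

Because labels are windowed averages, predicted fractions are a smoothed
version of the true ones; the per-cohort summary therefore reports the
regression line (slope, intercept) alongside Pearson's r — a non-zero
intercept is expected, not a defect. AUROC uses the rank (Mann–Whitney)
formulation with midrank ties; the Youden cutoff scans the observed
fractions with the at-or-above decision rule and breaks ties toward the
lower cutoff. The survival dichotomy defining "responder" (e.g. 14 days)
is cohort-dependent and passed in by the analyst
(`responder_from_survival`). Kaplan–Meier, log-rank and Cox modelling are
routine and left to standard survival tooling; `longitudinal_table`
formats per-subject trajectories (with deltas from pre-therapy) for exactly
that purpose.

## The synthetic phantom

Each synthetic slice is a rotated ellipse of tumor on a 64×64 MRI grid
(histology modelled at an integer multiple, default 8× — the true
histology-to-MRI resolution ratio after downsampling is not knowable from
the study design, so it is a free parameter). Perfusion structure drives
everything: a well-perfused rim (smoothstep profile over the outer 35% of
the radius) and 0–3 Gaussian poorly perfused cores of random width
(0.25–0.55 of the tumor radius) and depth. The DCE curve per pixel is a
gamma-variate whose amplitude rises and whose onset delay and time-to-peak
shrink with perfusion — no pharmacokinetic model (Tofts, AIF) is intended
or needed, only rim/core contrast in AUC, slope and TTM, which are computed
from the simulated series *by the package's own DCE module*. T2\* tracks
perfusion (deoxyhemoglobin shortens T2\*); T2W is a structural field of low
informativeness (its default link weight is 0).

Per-pixel hypoxia probability is the logistic of a linear combination of
the five channels, each standardized by fixed generator reference
statistics (computed from the noise-free channel response over a uniform
perfusion grid, so the link is a deterministic property of the generator,
not of any particular cohort). The default coefficients
(−1.0, 0, −1.5, +1.5, −1.5 for T2\*, T2W, slope, TTM, AUC, intercept −0.8)
make hypoxia a steep, monotone function of local perfusion — a *strong*
link: poorly perfused cores are hypoxic with probability near 1, the rim
near 0. The resulting per-slice true fractions span roughly 0–0.6 with
most slices above 0.1, matching the reported spread in real cohorts where
models performed poorly only below ~10% hypoxia.

The PIMO raster is drawn at histology resolution by comparing the
(upsampled, Gaussian-smoothed, sigma 6 histology pixels) probability field
against a spatially correlated uniform field obtained by rank-transforming
smoothed white noise. This keeps the marginal positive rate equal to the
local probability — so the constant-link sanity case lands on
`plogis(intercept)` — while producing contiguous habitats rather than
Bernoulli speckle. Histology-frame data (raster, polygons, landmarks) are
warped by a known affine (`affine_true`, default: 6° rotation, 4% scaling,
(5, −3) pixel shift); landmarks map exactly under it, so the registration
stage can be validated to machine precision.

What the phantom does **not** emulate: scanner physics (B0 inhomogeneity,
relaxometry fitting), histology artifacts (tears, folds, missing tissue —
excluded upstream in real studies), staining chemistry, and deformable
tissue distortion (the true histology-MRI misalignment is affine here by
construction). Passing tests therefore demonstrate that the pipeline's
machinery is correct and that a learnable MR-hypoxia link is recovered
end-to-end — not that any particular animal-model performance level is
reproduced.

## Numerical choices and degenerate inputs

* Otsu on a constant tissue region, single-class training labels, empty
  tumor masks, single-class response records and sub-3-slice correlation
  cohorts raise explicit errors rather than returning silent defaults.
* Two empty masks give Dice 0 with a warning (undefined overlap).
* Flat DCE pixels give slope 0; TTM ties take the earliest repetition;
  Otsu ties take the lowest level; cutoff-grid ties take the lowest cutoff.
* The split rule is `n_val = round(0.1 n)`, `n_test = round(0.3 n)`, train
  takes the remainder; subject-level grouping keeps all slices of a subject
  in one cohort when subject ids are supplied.
* Reproducibility is seed-exact: cohorts are bit-for-bit identical given
  `phantom_spec$seed`, and training given `train_config$seed`.

## Problem sizes

The bundled end-to-end checks run a 44-slice cohort (64×64 MRI grid, 8×
histology) with training patches capped at 600 per slice (≈16k patches)
for 10 epochs — sizes chosen so the whole cycle completes comfortably on a
single desktop CPU core while leaving the learning dynamics intact. The
null-link control (zero coefficients and intercept) runs five seeds at
48×48 / 4× scale and verifies that test-cohort correlations are centered
on zero, guarding against label leakage anywhere in the pipeline.

## Limitations

The CNN is trained per cohort; no transfer learning or pretrained weights
are involved, and nothing is claimed about cross-cohort generalization.
The registration model is per-slice 2D affine — adequate for mold-guided
sectioning, inadequate for free sectioning. The AUROC helper reports no
DeLong confidence intervals (bootstrap over `auroc` is straightforward if
needed). Real-data performance depends on acquisition and staining quality
outside this package's control.
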