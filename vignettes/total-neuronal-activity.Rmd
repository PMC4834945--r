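---
title: "Estimating relative metabolic activity from resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating relative metabolic activity from resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

FDG-PET measures resting cerebral glucose metabolism, but it is mildly
invasive and not available everywhere. Resting-state BOLD fMRI is cheap and
non-invasive, and its slow spontaneous fluctuations are thought to be of
neuronal origin. `neurotot` implements a fully automated pipeline that turns
a single resting-state fMRI acquisition into a scalar map of *relative*
activity that can stand in for a metabolic map in group statistics — it does
not, and cannot, estimate absolute uptake values.

The pipeline has four stages:

1. **Spatial ICA.** The 4-D BOLD volume is presmoothed (8 mm FWHM by
   default), each voxel's mean is removed, the frames-by-voxels matrix is
   reduced by SVD, and a symmetric FastICA rotation maximizes the
   non-Gaussianity of the spatial maps. Each map is standardized to z-scores
   over the analysis mask.
2. **Fingerprinting.** Each component is summarized by an 11-dimensional
   spatio-temporal feature vector that deliberately ignores *where* the
   component lives (so it survives the gross anatomical distortions of
   severely injured brains): spatial clustering of supra-threshold voxels,
   |skewness|, excess kurtosis and histogram entropy of the z values, lag-1
   autocorrelation and histogram entropy of the timecourse, and spectral
   power fractions in five bands (0–0.008, 0.008–0.02, 0.02–0.05, 0.05–0.1,
   0.1–Nyquist Hz). Neuronal sources carry their energy at 0.01–0.1 Hz in
   sparse, clustered maps; artifacts are faster and live at the brain
   boundary.
3. **Classification.** A support vector machine labels each component
   neuronal or non-neuronal. Both a linear and an RBF kernel are tuned over
   log10 C in −1…8 and (for the RBF) gamma in 0.1…1 by *nested*
   leave-one-subject-out cross-validation: the outer loop holds out one
   subject, the inner loop selects the hyperparameters on the remaining
   subjects, and ROC-AUC on the held-out subject estimates generalization
   without optimistic bias. Expert labels of "undefined" are excluded from
   both fitting and scoring.
4. **The total map.** The selected neuronal z-maps are combined voxelwise
   as the sum of the square root of their absolute values, smoothed with a
   16 mm kernel, and proportionally scaled to an in-mask mean of 100. The
   square root de-sparsifies the summed map: ICA is driven toward sparse
   maps, but time-averaged metabolic maps are not sparse, and compressing
   the tails moves the value distribution toward the near-normal shape of a
   metabolic map. The exponent is exposed (`exponent`, default 0.5).

The resulting map is compared with a metabolic map by Pearson correlation
over a gray-matter mask (probability ≥ 0.1), and groups are compared with a
voxelwise 2×2 factorial design (machine × group) with pooled-variance cell-
means t statistics, Benjamini–Hochberg FDR control per contrast, and
conjunction (intersection of individually significant masks) across
machines.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_components` | 30 | ICA model order (fixed, not estimated) |
| `presmooth_fwhm_mm` | 8 | per-frame smoothing before ICA |
| `final_smooth_fwhm_mm` | 16 | smoothing of the total and metabolic maps |
| `gm_threshold` | 0.1 | gray-matter probability cutoff (≥ convention) |
| `exponent` | 0.5 | power applied to abs z before summation |
| `q` | 0.05 | FDR level per contrast |
| log10 C | −1…8 | SVM regularization grid |
| gamma | 0.1…1 step 0.1 | RBF kernel width grid |

The 16 mm kernel is the single most influential choice for the subject-level
correlation: it matches the effective resolution of a smoothed metabolic map
and washes out residual ICA misattribution. The gray-matter threshold
deliberately includes low-probability voxels so the comparison covers the
whole cortical ribbon.

## The synthetic phantom

No clinical data ship with the package; every stage is validated on a
synthetic phantom (`make_phantom()`) with known ground truth:

* an ellipsoidal "brain" inscribed in the grid (default 20×20×12 voxels of
  3 mm), with gray-matter probability 0.9 inside, 0.05 on the one-voxel
  boundary shell and 0 outside — so the 0.1 threshold is exercised
  nontrivially;
* *neuronal* sources: compact blobs covering 5% of in-brain voxels placed by
  farthest-point sampling (well-separated, as spatial independence assumes),
  with timecourses that are sums of 3–5 sinusoids on Fourier-grid
  frequencies inside 0.01–0.1 Hz (on-grid frequencies keep spectral leakage
  out of the band-power contracts);
* *artifact* sources: contiguous same-sign patches on the boundary shell
  (mimicking scalp/motion artifacts) with 0.15–0.25 Hz timecourses;
* i.i.d. Gaussian sensor noise (SD 0.5 by default, a moderate SNR for
  smoothed 3 T resting-state data);
* a **metabolic surrogate** defined as what an ideal pipeline would produce:
  the 16-mm-smoothed voxelwise sum of the square root of the absolute
  *z-scored* ground-truth neuronal maps. Defining the surrogate on the
  z-scored maps (rather than the raw source maps) matters: z-scoring gives
  every component a nonzero background level inside the brain, and with
  zero-padded smoothing that background becomes a brain-shaped gradient; by
  construction the surrogate shares it, so perfect recovery yields a
  correlation of exactly 1 and any shortfall is attributable to ICA and
  classification errors, not to the definition itself.

The phantom does **not** emulate hemodynamics, physiological (cardiac or
respiratory) noise, scanner drift, or lesioned anatomy. Passing tests
therefore demonstrate that the pipeline's machinery is correct and
recovers known ground truth under its own model assumptions — not that the
method is clinically valid on real acquisitions.

The labeled fingerprint corpus (`make_fingerprint_corpus()`, default 19
subjects × 30 components with label proportions 224:248:98 for
neuronal : non-neuronal : undefined) draws features from class-conditional
Gaussians around two prototype fingerprints. The prototypes were calibrated
once against fingerprints measured on phantom components run through the
default pipeline, so that `class_separation = 3` — the corpus used
throughout the tests — reproduces realistic neuronal and artifact
fingerprints and a classifier trained on the corpus transfers directly to
phantom-derived components. Per-feature noise SDs are proportional to the
prototype gap and rescaled so the standardized distance between class means
equals `class_separation` exactly; "undefined" samples sit at the midpoint
with 1.5× the spread; each subject receives a small random offset (0.25 SD)
so that leave-one-subject-out folds are genuinely harder than random splits.
A `geometry = "radial"` variant places one class at the origin and the other
on a shell of the standardized feature space — separable only by a nonlinear
boundary, which is the regime where the RBF kernel must beat the linear one.

## Numerical choices

* **Smoothing** is separable Gaussian convolution with
  sigma = FWHM / (2·sqrt(2·log 2)) voxels per axis and zero padding
  (SPM-like); mass is not conserved at the grid faces, which is documented
  behavior, and the impulse-response FWHM is verified to 2%.
* **z-scoring** uses the population SD; maps are exactly 0 outside the mask.
* **FastICA** uses the logcosh contrast with symmetric decorrelation and a
  convergence test against the full-step fixed point (tolerance 1e-6, up to
  1000 iterations). The plain symmetric iteration can enter a limit cycle
  between equivalent solutions; the step is therefore adaptively damped, but
  only once a near-converged iterate starts oscillating, so the usual
  trajectory is the classic one. Up to 5 deterministic reseeded restarts;
  non-convergence after that is an error naming the seed. Components are
  ordered by explained variance with positive-skewness sign convention, so
  a fixed seed yields a bitwise-reproducible decomposition.
* **SVM training** is an L1-loss dual coordinate-descent solver (compiled;
  regularized bias via feature/kernel augmentation, warm starts along the
  increasing C path for the RBF grid, iteration-capped so cost is bounded
  even at C = 1e8). Decision-value agreement with libsvm is asserted in the
  test suite at moderate C. Selection ties break toward the smallest C then
  the smallest gamma (preferring smoother boundaries); the deployed model is
  refit on all labeled samples with the modal selected parameters.
* **ROC-AUC** is the rank-based Mann–Whitney statistic with ties counted
  one half.
* **BH-FDR** is the step-up procedure over in-mask voxels, applied per
  contrast (the per-contrast convention of standard neuroimaging software),
  reporting the p-threshold actually used.
* **Factorial model**: voxelwise cell means with pooled variance and
  df = N − 4; one-sided p-values per directed contrast; "preserved"
  contrasts are exact negations of the corresponding decrease contrasts.
* **Motion**: displacement is the mean norm of translation relative to the
  first frame; speed is the mean frame-to-frame translation norm per frame
  (per second on request). Rotations are carried but enter only when an
  arc radius is supplied (default off), since the summary metrics are
  defined on translations.

## Design choices that were genuinely open

* The eleven fingerprint features are this package's concrete instantiation
  of "spatial sparsity + low-frequency energy + information content +
  coherence"; lag-1 autocorrelation stands in for the coherence measure.
  Spatial skewness is reported as an absolute value so every feature is
  invariant to the arbitrary sign of an independent component.
* Proportional scaling normalizes to in-mask mean 100. The alternative
  grand-mean conventions change absolute values only; no correlation or t
  statistic is affected.
* The analysis (ICA) mask is the brain support (gray-matter probability
  above a small threshold, 0.01), while correlations and scaling use the
  0.1 gray-matter mask; artifacts live outside gray matter and must be
  visible to the ICA to be separable.
* Maps are never resampled implicitly: affine mismatches beyond 1e-4 are
  errors, because coregistration is out of scope.
* No re-standardization is applied after the voxelwise summation; the
  subsequent proportional scaling fixes the scale.
* Conjunction uses the conjunction-null (intersection) reading: a voxel must
  be individually significant in both contrasts.

## Problem sizes used in the tests

Unit tests run on a 14×14×10 phantom with 120 frames; the end-to-end
property checks use the default 20×20×12 phantom with 300 frames, 4 neuronal
and 3 artifact sources, a 19×30 separation-3 corpus for classifier training
(full parameter grids), 5 phantom subjects per end-to-end check, 20 subjects
for the activity-versus-component-count relation, and 200 simulated null
designs for the FDR calibration. These sizes were chosen so that the full
suite documents the method's behavior while remaining comfortable to run on
a laptop.

## Known limitations

* The phantom's linear mixing with sinusoidal sources is far simpler than
  real BOLD dynamics; classifier transfer to real data would require a
  corpus of expert-labeled real components.
* Fixed model order (30) is assumed adequate; no order selection is
  performed.
* The factorial design supports exactly the 2×2 machine-by-group layout; no
  covariates.
* Absolute metabolic quantification (SUV) is explicitly out of scope: only
  relative spatial patterns are estimated.
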