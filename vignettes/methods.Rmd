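---
title: "Methods: synthetic-cohort CT radiomics for growth patterns of liver metastases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-cohort CT radiomics for growth patterns of liver metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Colorectal liver metastases grow against the surrounding liver in distinct
histopathological growth patterns (HGPs). The two frequent pure patterns —
desmoplastic (dHGP), with a fibrous rim separating tumor from liver, and
replacement (rHGP), with tumor cells replacing hepatocytes at the interface —
differ strongly in prognosis, yet can only be scored microscopically on
resection specimens. This package implements a radiomics classifier of pure
dHGP vs pure rHGP from portal-venous-phase CT: region-of-interest definition,
a fixed 564-feature bank, feature-reliability screening, scanner
harmonization, a random search over preprocessing+classifier workflows with
top-k ensembling, and a 100-fold patient-grouped random-split evaluation with
confidence intervals that respect split overlap.

The patient CTs behind the original analysis are not distributable, so the
package treats the *statistical structure* of that cohort as its stated
world and implements it as a first-class, tested synthetic generator. A green
pipeline test therefore establishes that the machinery measures what it
claims on data with the assumed structure — not that the biological effect
size on real CT is reproduced.

## The synthetic cohort: what it emulates, and what it does not

Each patient owns one volume (default 64×64×24 voxels; tests and the
acceptance runs use 48×48×16 for desk-scale runtime): a smooth parenchyma
field (Gaussian random field, mean 100 HU, sd 10 HU, correlation length ~6
in-plane voxels) holding 1–3 non-overlapping ellipsoidal lesions
(hypodense, ~70 HU core). Lesion multiplicity uses P(1, 2, 3) =
(0.80, 0.17, 0.03), giving a mean of 1.23 lesions/patient so that 76
patients yield ~93 lesions as in the study cohort; patients carry one class
label (the study's Table 1 classifies patients, 37 vs 39), and lesions
inherit it.

**Class signal.** Two effects scale linearly with `texture_effect`: a rim
intensity offset (+15 HU × effect on the outer 2-voxel shell, the imaging
correlate of a desmoplastic fibrous rim) and a coarser interior texture for
dHGP (texture correlation length 1 + 0.8 × effect voxels vs 1). At
`texture_effect = 0` the two classes are draws from one distribution — the
null world used for calibration tests. The default of 1 was chosen once as a
clearly separable world (rim contrast on the order of real enhancement
differences) and is used for the signal-recovery criterion; it is *not* an
estimate of the real dHGP/rHGP effect size, which the null-vs-signal pair
deliberately brackets.

**Observers.** A hidden reference mask per lesion is perturbed per observer:
the mask indicator is blended half-and-half with its Gaussian-smoothed copy
(so zero perturbation reproduces the mask exactly), a smooth random field is
added with magnitude `mag`, and the result re-thresholded at 0.5. Every
voxel flips at most once as `mag` grows, making Dice-vs-input monotone
non-increasing, so bisection on `mag` hits any reachable Dice target;
targets are refused (error) for masks under ~30 voxels, where single-voxel
flips exceed the ±0.05 tolerance. STUD2 is generated as a perturbation *of
STUD1* at Dice 0.80, reproducing the intra-observer repeat; PhD and RAD are
independent perturbations of the reference at 0.82, calibrated once so the
emergent mean pairwise inter-observer Dice is ≈0.69 (the pairwise Dice of
two independent perturbations is systematically lower than either's Dice to
the reference). The CNN observer is erosion-biased (conservative outlines)
and misses each lesion with probability 8/93, substituting the radiologist's
mask verbatim — the deployment rule of the study.

**Acquisition.** Manufacturers are drawn with probabilities 43:16:16:1
(Siemens, Philips, Toshiba, GE); each applies an affine intensity distortion
(e.g. Philips +12 HU, ×1.06) so that harmonization has a real target; the
single-GE-scan situation that forces singleton-batch exclusion occurs with
realistic probability. Slice thickness, pixel spacing, tube current and kVp
are drawn near the study's Table-1 medians. Clinical covariates are
simulated independent of the label (the study found no significant clinical
differences); an optional `label_association` knob exists for sensitivity
analyses and defaults to 0.

Not emulated: anatomy (liver shape, vessels, neighbouring organs),
reconstruction-kernel texture, partial-volume effects, and any real
correlation between lesion size and class. Results on this generator
validate the pipeline's statistics, not clinical performance.

## Feature bank

The manifest (single source of truth, `feature_manifest()`) fixes 564 names:
15 first-order intensity + 21 shape + 96 GLCM + 54 LBP + 216 Gabor + 54 LoG
+ 54 vesselness + 54 local phase. The published parameter grids fix the
families (GLCM: 16 gray levels, distances 1 and 3, angles 0/45/90/135; LBP:
r/n = 1/8, 2/12, 3/16; Gabor: f = 0.05/0.2/0.5 with four angles; LoG:
σ = 1/5/10 px; vessel: full/edge/inner; phase: monogenic phase, phase
congruency, phase symmetry) but not the per-family counts; the partition
above is this package's reconstruction and changing it is a breaking change.

Decisions a reader should know:

* **2-D per-slice texture.** Segmentations are drawn per transverse slice
  and CT spacing is strongly anisotropic (~0.74 mm in-plane vs 2–5 mm
  between slices), so all filter families operate on axial slices and are
  aggregated over slices by mean and sd. Filter maps depend on the image
  only, so they are cached per (volume, slice) and shared across observers
  and ROIs.
* **Gray levels.** Equal-width binning of the ROI's [min, max] into 16
  levels; the binning rule is not fixed by the published grids.
* **Gabor frequencies** are cycles/pixel; σ = 0.56/f (≈1-octave bandwidth);
  kernels are DC-corrected so constant inputs give zero response.
* **LoG** kernels are scale-normalised (σ²∇²G), so blob responses peak at
  σ ≈ R/√2 — tested against the analytic kernel value.
* **Vesselness** is single-scale 2-D Frangi (σ = 1.5, bright structures);
  edge/inner split by 2-pixel in-plane erosion.
* **Local phase** uses a 3-scale log-Gabor monogenic signal
  (ω₀ = 0.25, 0.10, 0.04; σ-ratio 0.55); phase congruency is the simplified
  energy/total-amplitude form. All three maps are contrast-invariant by
  construction (relative ε in the denominators).
* **Degenerate inputs** (constant ROI, masks thinner than a GLCM offset,
  slices with <5 mask pixels) zero-fill the affected statistics rather than
  propagate NaN; `extract_all()` guarantees 564 finite values or errors on
  an empty mask.

## Reliability and harmonization

ICC uses the two-way random-effects, absolute-agreement, single-measurement
form — the family presumed by the good/excellent thresholds (0.75/0.90)
cited in the field — computed from ANOVA mean squares and tested to 1e-10
against an `aov()` oracle. It is computed on the three human observers
(STUD2, PhD, RAD) by default, matching the multi-observer training set; the
published analysis does not state which observer subset entered its ICC.

ComBat is the standard no-covariate location/scale model: per-feature
standardization, per-batch location (γ) and scale (δ) estimates shrunk by
parametric empirical-Bayes priors (normal / inverse-gamma, moment-matched),
iterated to convergence. Batches are manufacturer, or manufacturer ×
slice-thickness above/below the cohort median; singleton batches are
excluded and passed through unchanged. Using the class label as a ComBat
moderation variable is deliberately unsupported — the source analysis flags
it as leakage. Two numerical choices are worth stating: a single batch is an
exact no-op (nothing to remove; the raw estimator would still rescale by a
finite-sample factor), and the `eb = FALSE` mode subtracts the direct batch
estimates — the only estimator that equalizes batch means to machine
precision, which the exact-removal acceptance check exercises; the EB mode
is checked by parameter recovery (γ separation ≈ injected offset) instead.

## Workflow search and evaluation

A candidate workflow = scaler (z-score / robust / min-max / none) ×
selector (none, or top-k by univariate rank-AUC, k log-uniform on 5–60) ×
imbalance handling (none / random oversampling) × one of eight classifiers
with hyperparameters drawn from declared priors (`workflow_priors()` is the
one place they live). Classifier backends: glmnet (elastic-net logistic),
MASS LDA/QDA (projected onto ≤ n−5 principal components when p ≈ n),
Gaussian naive Bayes, a least-squares SVM (kernel ridge on ±1 labels,
linear/RBF, Platt-calibrated), and random forest / AdaBoost / gradient
boosting on a weighted CART regression tree in C++ (for 0/1 labels variance
splitting ≡ Gini). Exact equivalence to any particular reference library is
a non-goal; the boosting learners subsample ≤64 features per tree for
desk-scale runtime.

Candidates are ranked by mean weighted F1 over five patient-grouped
stratified 85/15 internal splits (the published pipeline does not state its
ranking metric; AUC is available via `metric = "auc"`), ties broken by draw
index. The top k are refit on the full training rows — refit-on-full was
chosen over keeping internal-split fits, which the source leaves open — and
predictions are the mean member probability with decision threshold 0.5.
All training-side state (imputation medians, scaler parameters, variance
filter, univariate ordering, ICC filtering, ComBat parameters) is fitted
strictly inside each outer training set; a sentinel test corrupts the
test-observer rows two different ways and asserts bit-identical fitted
ensembles.

Outer evaluation: 100 (desk scale 10) stratified patient-grouped 80/20
splits. Multi-observer training rows are the three human observers' copies
(3× rows); test rows are always the CNN observer, including
fallback-substituted masks. Iterations with a single-class test set have no
AUC and are excluded from averaging (counted and reported). CIs use the
corrected resampled t statistic with variance factor 1/k + n_test/n_train,
with lesion counts entering the ratio; the correction makes the interval
√26 ≈ 5.1× wider than the naive t interval at k = 100 and a 0.25 ratio. ROC
bands are fixed-width around the vertically averaged curve, with the
smallest half-width covering ≥95 % of the resampled curves.

## Desk-scale budgets and what the acceptance runs mean

The acceptance runs use 28 patients on a 48×48×16 grid, 10 outer
iterations, 1,000 candidates, ensemble of 10 — chosen once for ~15-minute
single-CPU runtime. The null run (texture_effect = 0) must produce an AUC
interval covering 0.5: it calibrates the whole chain against optimism
(leakage, selection bias, CI mis-scaling would all break it). The signal
run (texture_effect = 1) must reach test AUC ≥ 0.85: it verifies the chain
can transport a real class difference through observer variability, batch
effects and the CNN-observer domain shift. The pair brackets the published
mid-performance regime (AUC ≈ 0.69) without claiming to reproduce it —
that number depends on the unavailable CTs.

## Known limitations

* Morphology uses a voxel-based 6-connected element; ring width is in
  voxels (default 2/side), not millimetres — the source does not state the
  unit, and anisotropic mm-calibrated kernels would be overkill at phantom
  scale.
* The 564-feature partition across families is a reconstruction (see
  above); per-family counts were never published.
* Phase congruency is the simplified single-pass energy form, not the full
  noise-compensated estimator.
* The NIfTI reader/writer supports the little-endian single-file subset the
  pipeline writes; it is not a general NIfTI implementation.
* LS-SVM differs from a hinge-loss SVC in its loss; with Platt calibration
  the ranking behaviour is close, and the search treats it as one of eight
  interchangeable candidates.
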