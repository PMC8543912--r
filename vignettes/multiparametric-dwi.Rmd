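---
title: "Multiparametric multi-b-value DWI: models, maps, radiomics and the classification benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric multi-b-value DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mbdwi` analyses multi-b-value diffusion-weighted MRI (DWI) of focal
lesions: it fits four diffusion signal models voxel by voxel, derives nine
quantitative parameter maps, extracts a 100-feature radiomics vector per
map from a lesion mask, and benchmarks four classifiers for
benign/malignant discrimination against simple lesion-mean metrics. This
vignette documents the models, the estimation and numerical choices, the
synthetic phantom generator, and the limits of what the synthetic test
evidence shows.

## The four signal models

All models describe the normalised magnitude signal $S_b/S_0$ at diffusion
weighting $b$ (s/mm²); diffusivities are in mm²/s, so $b\cdot D$ is
dimensionless.

* **Mono-exponential (ME)** — $S_b/S_0 = e^{-b\,\mathrm{ADC}}$. Fitted
  twice: on the full scheme (`ADC_all-b`) and on the classic two-point
  subset $b\in\{0,1000\}$ (`ADC_0-1000`), where the estimate is the exact
  closed form $\ln(S_0/S_{1000})/1000$.
* **Biexponential IVIM** — $S_b/S_0 = (1-f)e^{-bD} + f e^{-bD^*}$, with
  tissue diffusivity $D$, pseudo-diffusion $D^*$ of the microvascular
  compartment and perfusion fraction $f\in[0,1]$. We impose $D \le D^*$ as
  the identifiability convention: the two exponentials are exchangeable,
  and in tissue the perfusion compartment decays faster by an order of
  magnitude.
* **Stretched exponential (SE)** — $S_b/S_0 = e^{-(b\,\mathrm{DDC})^\alpha}$
  with heterogeneity index $\alpha\in(0,1]$; $\alpha = 1$ is
  mono-exponential decay and smaller $\alpha$ means a broader intravoxel
  distribution of diffusion rates.
* **Diffusion kurtosis (DKI)** — $S_b/S_0 = e^{-bD + b^2D^2K/6}$, $K\ge 0$
  the excess kurtosis; $K=0$ is Gaussian diffusion. The quadratic exponent
  reaches its minimum at $b = 3/(DK)$ and re-grows beyond it, which is
  nonphysical; `dki_signal()` evaluates the equation everywhere, but the
  fitter caps predictions at that minimum (`dki_b_max()`). With the
  default scheme ($b \le 2500$) and physiological parameters the cap is
  rarely active, and parameter recovery is only claimed inside the
  validity range.

The degenerate reductions (IVIM at $f=0$, SE at $\alpha=1$, DKI at $K=0$
all equal ME) hold to machine precision and are asserted as properties in
the test suite.

## Acquisition scheme

The default scheme is 13 b-values, $\{0, 10, 30, 50, 100, 150, 200, 500,
800, 1000, 1500, 2000, 2500\}$ s/mm²: dense below 200 to resolve the
perfusion compartment, extended to 2500 to condition the kurtosis term.
This is a configurable stand-in for a clinical multi-b protocol, not a
fixed standard; any strictly increasing scheme containing 0 is accepted
(the two-point ADC map additionally needs $b=1000$).

## Voxel-wise estimation

Processing follows the conventional chain: a Gaussian pre-filter of 3 mm
full width at half maximum (σ = FWHM/(2√(2 ln 2)) in mm, converted per
axis to voxels via the voxel spacing; truncated-kernel renormalisation at
the volume edge, so constant volumes are unchanged), then bounded
Levenberg–Marquardt least squares per voxel in the signal domain.

Numerical choices that matter:

* **Free scale.** $S_0$ is a free per-voxel parameter rather than the
  measured $b=0$ intensity, so smoothed $b=0$ noise does not bias every
  ratio; $R^2$ is computed between observed and model-predicted signals
  over the fitted b-subset.
* **Seeding and bounds.** All fits are seeded from a signal-weighted
  log-linear regression (for DKI, a log-quadratic regression, which is
  exact on clean data); SE starts at $\alpha = 0.9$, DKI at $K = 0.5$ when
  the quadratic seed is unusable. Bounds: ADC, D, DDC ∈ [10⁻⁶, 4×10⁻³]
  mm²/s (free-water ceiling), $D^*$ ≤ 0.5 mm²/s, $f$ ∈ [0,1], $\alpha$ ∈
  [0.01, 1], $K$ ∈ [0, 3]. Bounded fits keep low-SNR voxels from
  diverging.
* **Segmented IVIM (default).** Step one estimates $D$ and the
  extrapolated intercept from a log-linear fit on $b \ge 200$ s/mm²
  (where the perfusion compartment has essentially decayed); step two fits
  $f$ and $D^*$ over all b with $D$ frozen. This is the stable community
  default at clinical SNR. It carries a small perfusion-contamination
  bias in $D$ (~1% at typical breast parameters, since $f\,e^{-200 D^*}$
  is not exactly zero), so the exact-recovery tests use the documented
  `ivim_mode = "full"` joint fit, which is seeded from the segmented
  estimate and recovers noise-free model data to ~10⁻¹⁴. We also tried an
  iterated perfusion-subtraction refinement of the segmented fit: it is
  exact noiselessly but amplifies noise (median $D$ error roughly doubles
  at SNR 30), so it was not retained.
* **Invalid voxels.** All-zero or non-positive $b=0$ signals flag the
  voxel invalid; it is `NA` in every map and excluded from means, QC and
  radiomics.
* **QC rule.** A lesion is excluded when the mean $R^2$ over its mask is
  below 0.8 for any fitted nonlinear model; the comparison is strict, so
  exactly 0.8 passes.

## Radiomics

`extract_features()` computes 100 features per (map, mask) pair: 18
first-order, 14 shape, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM — the
standard 3D definitions of the radiomics literature, implemented directly
in the package. Choices:

* **Discretisation** is fixed bin width, 1/25 of each map's physiological
  range (e.g. 4×10⁻³/25 mm²/s for diffusivity maps), so gray levels are
  comparable across subjects — the usual requirement for texture features
  on quantitative maps. The bin width is a parameter of every extraction.
* **Texture aggregation**: GLCM and GLRLM matrices are computed for the 13
  unique 3D direction offsets and averaged as matrices before features are
  taken; GLSZM zones and GLDM dependences use the full 26-neighbourhood
  (dependence tolerance α = 0).
* **Shape**: volume is voxel-count volume; surface area uses the coarea
  formula on a half-voxel-smoothed indicator (gradient-magnitude
  integral), which converges to a discretised sphere's area within ~1% at
  radius 10 voxels — sphericity therefore approaches 1 for spheres, which
  is asserted in tests. The set includes sphericity and its reciprocal
  (spherical disproportion), three maximum-diameter variants restricted to
  coordinate planes, and PCA axis lengths ($4\sqrt{\lambda}$).
* **Mean metrics** (mADC, mD, mD\*, mf, mDDC, mα, mK, mD_kurt) are plain
  lesion means of the maps and coincide with the first-order Mean feature.
* **Reproducibility** is ICC(2,1) — two-way random effects, absolute
  agreement, single rater — per feature between two readers'
  segmentations; features with zero between-subject variance are flagged
  undefined rather than given a value.

## Classification benchmark

Subjects are split once, stratified 50/50 (largest-remainder rounding with
a deterministic tie-break; a 542-subject cohort with 333 malignant cases
gives a 271-subject training half). Four classifiers consume the identical
per-map 100-feature matrix and split, making AUC comparisons paired by
construction:

* **RF** — 100 trees, maximum depth 3, impurity importances normalised to
  sum to 1; raw features (trees are scale-invariant).
* **L1R-LR** — L1-penalised logistic score; features standardised by
  training statistics; the sparsity weight is chosen by seeded internal
  cross-validation (fixed moderate penalty on very small training sets)
  and recorded in the model.
* **PCA-LR** — univariate Wilcoxon rank-test prefilter to the 100 lowest P
  values (training data only), 10 principal components, linear logistic
  score.
* **SVM-RBF** — cost and kernel scale tuned by a small seeded grid search
  with internal stratified CV on the training half.

"Linear regression" classifiers produce continuous scores (linear
predictors), which is what ROC analysis needs; hard labels are only formed
at Youden thresholds for McNemar comparisons. Repeated stratified k-fold
cross-validation (10 folds, re-shuffled each repeat, all preprocessing
refitted inside each training fold) is available for stability and
feature-frequency reporting; the held-out evaluation refits each model on
the full training half and scores the untouched test half once, which we
chose over averaging the CV models' test scores because it keeps a single
well-defined model per (map, classifier) cell (the ensemble alternative is
a config option of the CV machinery, not of the headline pipeline).

## Evaluation

AUC is the Mann–Whitney statistic with midrank ties. Confidence intervals
are class-stratified bootstrap percentile intervals (2000 resamples by
default); coverage is verified at ≈95% by simulation in the acceptance
tests. Operating points maximise the Youden index on the scored data, with
ties broken toward sensitivity. McNemar's test compares two methods'
dichotomised predictions (each at its own Youden threshold) on the same
subjects: exact two-sided binomial for ≤ 25 discordant pairs,
continuity-corrected χ² above; when repeated (the protocol's 100 runs),
runs redraw stratified bootstrap replicates and the mean P value is
reported. The family-wise threshold is Bonferroni α/m with the
comparison count m = 23 as a config input. Image quality at the highest b
is SNR = lesion mean / background SD, CNR = (lesion − background means) /
background SD, contrast = ratio of means, with the background box
auto-placed as a 2-voxel slab along the lowest-mean volume face (always
air in the phantom geometry) and recorded in the output.

McNemar-on-AUCs deserves a note: McNemar compares paired classifications,
not AUCs, so dichotomisation at per-method Youden thresholds is the bridge
used here; both the threshold rule and m are parameters, not claims.

## The phantom generator

`make_cohort()` produces labelled cohorts with the statistical structure
the analysis assumes — and nothing more. Per subject: an ellipsoidal
lesion (semi-axes jittered around 5×4×3 mm, smooth boundary irregularity)
inside a body compartment surrounded by air, on a 24×24×12 grid at
1.5×1.5×2 mm. Signals are generated from the IVIM model on ground-truth
(D, D*, f) fields; because a two-compartment mixture is not
mono-exponential, SE and DKI fits are well-posed on the same decay and
their fitted α and apparent K inherit class contrast from the (D, f, D*)
draws (malignant: higher K, lower α). Class-conditional subject means
default to malignant D ~ N(0.95, 0.15)×10⁻³ and benign D ~ N(1.55,
0.20)×10⁻³ mm²/s, with slightly higher f and D* and double the
intra-lesion heterogeneity for malignant lesions; these are synthetic
choices from the breast-DWI literature range — the source data report no
per-class parameter statistics — and are exposed as tuning knobs
(`class_params`), not validated quantities. Heterogeneity is injected as
spatially correlated Gaussian random fields (correlation length 2.5 mm) on
each parameter, which is precisely the mechanism that makes texture
features informative by construction.

Noise is Rician — each voxel becomes
$\sqrt{(S+n_1)^2+n_2^2}$ with i.i.d. Gaussians of SD σ — because
magnitude MR data is Rician and the near-noise-floor high-b regime makes
the distinction matter (air background is Rayleigh, mean σ√(π/2)). The
cohort's `snr` parameter targets the *measured* convention: lesion mean
over background-magnitude SD on the highest-b volume, so σ is set per
subject from its noiseless lesion signal at b_max divided by
(snr·√(2−π/2)). `add_rician_noise()` itself keeps the plain σ =
reference-mean/snr contract with the reference volume selectable.
Second-reader masks come from `perturb_mask()`: the mask indicator is
softened by a half-voxel Gaussian, a smooth random field scaled by the
magnitude (default 0.1, giving Dice ≥ 0.8 on typical lesions) is added,
and the result is re-thresholded within the softened support.

## What the synthetic evidence does and does not show

Passing tests on this generator demonstrate that the estimation chain is
*correct* (parameters are recovered at the stated tolerances, statistics
match their oracles, the pipeline is deterministic and leak-free), and
that under class-separable ground truth the radiomics random forest
recovers the separation (held-out AUC far above its label-shuffled
control). They do **not** show clinical performance: the phantom has no
anatomy, coil profile, EPI distortion or partial-volume structure, its
class separation is put in by hand, and with the default separation the
synthetic AUCs are far higher than anything reported on patients. Absolute
AUC values from the phantom are therefore properties of the generator
settings, not estimates of diagnostic accuracy.

## Problem sizes and reproducibility

Desk-scale defaults were chosen so the full chain is testable in minutes:
phantom grids of 24×24×12 voxels, cohorts of 200 subjects (123 malignant,
mirroring the 333:209 ratio at 542) for the acceptance benchmark, 10-fold
CV with a handful of repeats in examples, and 400–2000 bootstrap
resamples. Every stochastic step takes a seed, cohort subjects derive
their seeds from the cohort seed, and `run_pipeline()` derives all stage
seeds from one config seed, so equal configs are numerically identical;
RNG state is always restored, never leaked. The full-scale protocol
(542 subjects, 100 CV repeats, 100 McNemar runs) is reachable by changing
the config only.

## Known limitations

* Fits are per-voxel and independent; no spatial regularisation beyond the
  pre-filter.
* The DKI fit uses all b-values by default; a `b_max` restriction is
  available via `b_subset` but no automatic selection is attempted.
* Shape features use voxel-count volume and a smoothed-gradient surface
  estimate rather than an explicit surface mesh; for very small or very
  thin lesions (a few voxels across) the surface estimate is coarse.
* GLRLM/GLCM direction averaging assumes approximately isotropic voxels;
  strongly anisotropic spacing distorts direction-dependent texture.
* `mcnemar_paired()` compares dichotomised scores; it is not a test on the
  AUC difference itself.
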