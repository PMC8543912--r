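# mbdwi — multiparametric multi-b-value diffusion MRI analysis

`mbdwi` is an R package for quantitative analysis of multi-b-value
diffusion-weighted MRI (DWI) of focal lesions, aimed at researchers who want
to benchmark radiomics-based lesion classification against simple mean
diffusion metrics. It implements the full chain:

1. **Signal models.** Four voxel-wise diffusion models of the normalised
   signal S_b/S_0:
   - mono-exponential (ME): `exp(-b·ADC)`
   - biexponential intravoxel incoherent motion (IVIM):
     `(1-f)·exp(-b·D) + f·exp(-b·D*)`
   - stretched exponential (SE): `exp(-(b·DDC)^α)`
   - diffusion kurtosis (DKI): `exp(-b·D + b²·D²·K/6)`
2. **Voxel-wise fitting** (3 mm FWHM Gaussian pre-smoothing, bounded
   nonlinear least squares with a free per-voxel scale, segmented IVIM)
   producing the nine standard parameter maps — ADC_all-b, ADC_0-1000, D,
   D\*, f, DDC, α, K, D_kurt — with per-model R² maps and a lesion-level
   quality-control rule (exclude when mean R² < 0.8).
3. **Radiomics.** 100 features per (map, lesion mask) pair — 18 first-order,
   14 shape, 22 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM — hence 900 features per
   subject over the nine maps; lesion-mean metrics (mADC, mD, mD\*, mf,
   mDDC, mα, mK); inter-reader reproducibility via ICC(2,1).
4. **Classification benchmark.** Stratified 50/50 split, four classifiers —
   random forest (100 trees, depth 3), L1-regularised linear model,
   PCA-reduced linear model (univariate prefilter to 100 features, 10
   components), RBF SVM — with repeated stratified 10-fold CV, impurity
   feature importances, and held-out scoring.
5. **Evaluation.** Mann–Whitney AUC with stratified-bootstrap 95% CIs,
   Youden operating points (sensitivity/specificity/PPV/NPV), paired
   McNemar comparisons (exact binomial below 26 discordant pairs) under
   Bonferroni control (0.05/23 = 0.00217), and b=2500 image-quality
   metrics (SNR, CNR, lesion contrast).
6. **Synthetic phantoms.** A seeded Rician-noise lesion-phantom generator
   (ellipsoidal lesions with spatially correlated intra-lesion texture,
   class-conditional diffusion parameters, 542-like labelled cohorts) so
   the whole pipeline runs end-to-end without patient data.

## Worked example

```r
library(mbdwi)

# one synthetic malignant lesion at SNR 30
ph    <- make_lesion_phantom(lesion_phantom_spec("malignant"), seed = 42)
noisy <- add_rician_noise(ph$volume, snr = 30, mask = ph$mask, seed = 1)
suite <- generate_map_suite(gaussian_presmooth(noisy, 3), mask = ph$mask)

glance(suite)
#> # A tibble: 4 × 2
#>   model   mean_r2
#>   <chr>     <dbl>
#> 1 ME        0.996
#> 2 BE_IVIM   0.999
#> 3 SE        0.999
#> 4 DKI       0.999

qc_filter_lesion(suite, ph$mask)        # every model passes mean R² >= 0.8
mean_metrics(suite, ph$mask)
#> # A tibble: 1 × 9
#>   `mADC_all-b` `mADC_0-1000`       mD   `mD*`    mf    mDDC malpha    mK mD_kurt
#>        0.00107       0.00109 0.000969 0.00847 0.104 0.00110  0.858 0.515 0.00123

fv <- extract_features(suite$maps$D, ph$mask)
dplyr::count(fv, group)
#> # A tibble: 6 × 2
#>   group          n
#>   <chr>      <int>
#> 1 firstorder    18
#> 2 glcm          22
#> 3 gldm          14
#> 4 glrlm         16
#> 5 glszm         16
#> 6 shape         14
```

The mean R² values say each model explains over 99% of the per-voxel signal
variance across the lesion after smoothing (so the lesion passes QC), and
the feature table confirms the 100-feature vector in its fixed group
partition. At cohort scale, `run_pipeline(pipeline_config(...))` chains
simulate → fit → features → classify → evaluate into per-map AUC tables,
paired McNemar P values and forest importances (see the package vignette),
and `inst/cli/mbdwi` exposes the same stages as a command line.

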