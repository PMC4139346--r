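# lbptop

Gray-level invariant texture classification of structural brain MRI.

## The problem

Voxelwise comparison of T1-weighted MRI across scanners fails on raw
intensities: each scanner applies an approximately monotonic,
subject-specific transform of the tissue contrast. What survives is the
*ranking* of tissues (CSF < GM < WM), so any feature invariant under
strictly increasing intensity transforms is automatically harmonized
across scanners. The local binary pattern (LBP) is such a feature: for a
center pixel with intensity $I_c$ and its 8 ring neighbors $I_p$ in the
3×3 window,

$$\mathrm{LBP} = \sum_{p=0}^{7} s(I_p - I_c)\,2^p,\qquad s(x)=\mathbf{1}[x \ge 0],$$

an 8-bit code (256 possible labels) depending only on the signs of local
differences. Applied slicewise on the three orthogonal planes of a volume
(LBP-TOP), it yields three code volumes per subject that are bit-identical
under any strictly increasing gray-level transform of a tie-free image.

`lbptop` implements the full pipeline around that feature for classifying
patients (+1) against controls (−1) on linearly co-registered,
skull-stripped volumes:

* **NIfTI volume handling** (`read_volume()`, `check_same_grid()`, TSV
  subject manifests);
* **feature images** of three types — raw intensities (type 1),
  histogram-matched intensities (type 2), smoothed LBP-TOP code maps
  (type 3, Gaussian FWHM 4 mm) — via `feature_image()` /
  `collect_features()`;
* **two-step feature selection** (`fit_selection()`): voxelwise
  pooled-variance two-sample t-test on training subjects only
  (p < 0.001, uncorrected), then intersection with an anatomical
  binary mask (AMG, ENT, HIP, PHG, TL, LV, or their union OVALL);
* **linear-SVM classification** under repeated stratified 10-fold
  cross-validation with selection and standardization refit inside every
  training fold (`run_cv()`), metrics (accuracy, sensitivity,
  specificity, rank-based ROC/AUC; `compute_metrics()`), paired
  classifier comparison by McNemar's z = |b−c|/√(b+c) with the z > 1.960
  significance rule (`mcnemar_compare()`), and SVM weight maps
  back-projected to the template grid (`weight_map()`);
* a **synthetic phantom cohort generator** (`phantom_spec()`,
  `make_cohort()`) producing brain-like multi-tissue geometry with
  group atrophy, per-subject monotone scanner transforms (gamma sweep),
  noise and integer-voxel registration jitter — so every stage is
  testable without clinical data.

Results are tibbles throughout; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Generate a small strong-atrophy multi-scanner cohort, extract LBP-TOP
features, and cross-validate with two-step selection under the OVALL mask:

```r
library(lbptop)

spec <- phantom_spec(shape = c(32, 32, 32), n_per_group = 12,
                     atrophy_fraction = 0.6, ventricle_dilation = 1.4,
                     seed = 303)
cohort <- make_cohort(spec, "phantom_cohort")

features <- collect_features(cohort$manifest, type = 3,
                             brain_mask = cohort$template$brain_mask)
features
#> <lbp_features> type 3, 24 subjects, 3 plane(s) of 32 x 32 x 32 voxels (10048 valid)

cv <- run_cv(features,
             selection_criteria(alpha = 0.001, mask = cohort$masks$OVALL),
             cv_config(n_folds = 4, n_repeats = 2, seed = 99))
compute_metrics(cv)
#> <lbp_metrics> 24 subjects, 2 repeat(s)
#>   accuracy 0.854  sensitivity 0.917  specificity 0.792  AUC 0.962
```

Accuracy is the fraction of correctly classified subjects per repeat
(averaged over repeats), sensitivity/specificity the rates on the patient
(+1) and control (−1) classes, and AUC the Mann–Whitney concordance of the
pooled decision scores — 0.5 is chance, 1.0 perfect separation. Despite
every subject carrying a different scanner gamma (0.3, 1 or 3), the
invariant texture features separate the groups almost perfectly.

Comparing against the histogram-matched baseline on the same subjects:

```r
cv2 <- run_cv(collect_features(cohort$manifest, type = 2,
                               template = cohort$template,
                               brain_mask = cohort$template$brain_mask),
              selection_criteria(0.001, cohort$masks$OVALL),
              cv_config(n_folds = 4, n_repeats = 2, seed = 99))
mcnemar_compare(cv_correct(cv), cv_correct(cv2))
#> # A tibble: 1 × 5
#>       b     c     z     p significant
#>   <int> <int> <dbl> <dbl> <lgl>
#> 1     1     2 0.577 0.564 FALSE
```

At this easy effect size both classifiers do well, so their discordance is
small and not significant; on the harder moderate-atrophy cohort (the
`phantom_spec()` defaults) the three feature types separate clearly — see
below.

A thin command-line wrapper with subcommands `phantom`, `extract`,
`classify`, `compare` and `experiment` is installed at
`inst/cli/lbptop`.

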