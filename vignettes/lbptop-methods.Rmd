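---
title: "Gray-level invariant texture classification of brain MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-level invariant texture classification of brain MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Structural MRI collected across many scanners cannot be compared voxel by
voxel on raw intensities: each scanner applies what is, to a good
approximation, a subject-specific *monotonic* transform of the underlying
tissue contrast. The ranking of tissues is stable (in T1-weighted images
CSF is always darker than gray matter, which is darker than white matter),
but the gray values themselves are not. Any feature that is invariant under
strictly increasing intensity transforms is therefore automatically
harmonized across scanners.

The local binary pattern (LBP) is exactly such a feature. For a pixel with
intensity $I_c$ and its eight ring neighbors $I_0, \dots, I_7$ in the
$3\times3$ window, the code is

$$\mathrm{LBP} = \sum_{p=0}^{7} s(I_p - I_c)\, 2^p, \qquad
  s(x) = \begin{cases} 1 & x \ge 0 \\ 0 & x < 0,\end{cases}$$

an integer in $[0, 255]$ that depends only on the *signs* of the
neighbor-center differences. A strictly increasing transform of a tie-free
image preserves every sign, hence every code — this package treats that
invariance as an exact, testable contract, not an approximation. For 3D
volumes the operator is applied slicewise on the three orthogonal planes
(LBP-TOP): sagittal (y–z), coronal (x–z) and axial (x–y), giving three code
volumes per subject.

The pipeline classifies patients (+1) against controls (−1) from such code
volumes, using voxelwise statistics plus anatomical prior masks to select
features and a linear support vector machine under repeated stratified
cross-validation to measure discriminative power. Three feature
representations are compared throughout: type 1, the registered intensities
untouched; type 2, histogram-matched intensities (the conventional
cross-scanner standardization); type 3, smoothed LBP-TOP code maps.

All inputs are assumed skull-stripped and *linearly* registered to a common
template grid; registration itself is out of scope, and grid identity is
checked as shape plus voxel spacing only.

## Pipeline stages and their parameters

**Smoothing.** Raw LBP codes respond to boundaries but also to noise, so
the code maps are smoothed with a separable Gaussian before any statistics.
The default FWHM is 4 mm per axis; $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln
2} \cdot \mathrm{spacing})$ voxels (0.8493 voxels at 4 mm FWHM on a 2 mm
grid). The kernel is truncated at $4\sigma$ and renormalized; boundaries
are handled by symmetric reflection, which preserves constant maps exactly.
Codes are smoothed as ordinary real scalars even though they are nominal
labels — a deliberate fidelity choice: it is how the voxelwise-statistics
pipeline this package implements operates, and the smoothed maps feed a
discriminative model rather than any metric interpretation of code values.
Smoothing ignores the brain mask (the mask is applied later, at selection).

**Two-step feature selection.** Step one is data driven: at each valid
voxel of each plane, a pooled-variance two-sample Student's t between the
classes over the *training* subjects only, two-sided p from the t
distribution with $n_1 + n_2 - 2$ degrees of freedom, uncorrected, keeping
voxels with $p < \alpha$ (default $\alpha = 0.001$). No multiple-comparison
correction is applied, by design. Voxels with zero pooled variance are
never selected (their p is undefined). Step two is knowledge driven: the
surviving voxels are intersected with a binary anatomical mask — here the
phantom stand-ins named AMG, ENT, HIP, PHG, TL, LV and their union OVALL.
The selected (plane, voxel) coordinates are concatenated plane-major, in
array linear order within each plane, into one flat feature vector per
subject. The t-test domain is the common validity grid intersected with the
brain mask when one is present; whether selection should be brain-masked
was genuinely open, and restricting to the brain is the conservative
choice.

**Classification.** A linear SVM (cost $C = 1$ by default) on the selected
features, labels +1/−1. The kernel and $C$ were open choices; linear is
required anyway for the weight maps, which need primal weights, and $C$ is
exposed in `cv_config()`. Features are z-scored with statistics fit on the
training fold (toggleable); selection is refit inside every training fold.
Both choices exist to prevent leakage: no fitted component ever sees a test
subject, and the test suite asserts this by refitting from the recorded
per-fold training ids. Prediction is the sign of the decision score
(score 0 predicts +1); a fold whose selection retains zero voxels — which
can happen on null cohorts at strict $\alpha$ — scores every test subject 0
and predicts the training majority class.

**Cross-validation and metrics.** Stratified 10-fold cross-validation
repeated 30 times by default (tests and the acceptance script use fewer
repeats; see problem sizes below). Per repeat: accuracy, sensitivity (rate
on +1), specificity (rate on −1), and AUC from the repeat's pooled decision
scores by the rank (Mann–Whitney) formulation, ties counting one half. How
repeats should be pooled into single summary numbers was open; the summary
reports both the mean of per-repeat AUCs and the AUC of all scores pooled.

**McNemar comparison.** Two classifiers evaluated on the same subjects are
compared through their discordant-correctness counts: $b$ (A right, B
wrong), $c$ (A wrong, B right), $z = |b - c| / \sqrt{b + c}$, two-sided
normal p, significant at $z > 1.960$. No continuity correction by default
(the plain statistic is what the z-threshold rule describes), with the
corrected variant available as an option. $b = c = 0$ is defined as
$z = 0$, which also covers self-comparison. Correctness is taken from one
designated CV repeat so both classifiers are scored on a shared partition.

**Weight maps.** For one repeat, the absolute linear-SVM weight of each
(plane, voxel) is averaged over folds, counting 0 where the voxel was not
selected in a fold, then min–max normalized to $[0,1]$ over the
ever-selected voxels; never-selected voxels are 0, and a degenerate
constant weight field normalizes to 1 by convention. The per-plane maps are
written as NIfTI for inspection on the template grid.

## The phantom generator

`phantom_spec()` / `make_cohort()` generate cohorts with exactly the
statistical structure the method assumes, so every stage is testable
without clinical data:

* **Geometry.** Nested ellipsoids on a 64³ grid at 2 mm: an outer CSF
  shell, a GM shell, a WM core, two bilateral gray-matter "target" blobs
  inside the WM (hippocampus/amygdala stand-ins, radius 0.13 of the grid),
  and a central CSF-filled ventricle. Base intensities are
  piecewise-constant with T1-like ordering CSF (0.2) < GM (0.5) < WM (0.8).
* **Disease effect.** Patients get the target-blob radius multiplied by
  `atrophy_fraction` (default 0.9) and the ventricle radius by
  `ventricle_dilation` (default 1.1) *before* intensity assignment — the
  effect is a boundary shift, as in atrophy, not an intensity change.
* **Tie-breaking ramp.** A fixed low-amplitude (0.02) linear ramp with
  incommensurate axis weights is added to all brain voxels before any
  transform. It guarantees no two in-plane neighbors tie, so the LBP
  invariance property holds *exactly* under strictly increasing transforms;
  without it, ties would make the property unverifiable.
* **Scanner model.** Each subject receives one gamma exponent drawn from
  `scanner_gammas` (default {0.3, 1, 3}) applied to its [0, 1] intensities
  — a monotone contrast sweep standing in for acquisition variation such as
  flip-angle changes. The default sweep is wide enough that tissue
  intensity distributions overlap across scanners, which is what makes raw
  intensities unusable for voxelwise comparison.
* **Noise.** Additive Gaussian noise *after* the gamma transform (it
  models the scanner, not the anatomy), with standard deviation
  `noise_sigma` (default 0.1) times that subject's post-transform
  CSF-to-WM contrast, so signal-to-noise is comparable across simulated
  scanners. Exact-invariance experiments use `noise_sigma = 0`;
  classification experiments use noise.
* **Registration jitter.** A per-subject integer-voxel translation, up to
  `jitter_mm` (default 2 mm = 1 voxel), applied to image and ground-truth
  labels together. Integer shifts keep the ground truth exactly alignable;
  sub-voxel resampling would confound the exact LBP oracle.
* **Masks.** Analytic envelopes of the noiseless template geometry, padded
  by 2 voxels plus the worst-case jitter so they cover both groups: dilated
  spheres around each target blob (AMG, HIP), two GM-shell sectors (ENT,
  PHG), a large lobe sector (TL), the dilated ventricle envelope (LV), and
  OVALL, the voxelwise OR of the six.
* **Determinism.** All per-subject randomness derives from per-subject
  seeds drawn once from `spec$seed`; the same spec and seed reproduce the
  cohort byte for byte, and generation never disturbs the caller's RNG
  stream.

The default parameters were designed, and then frozen, so that the cohort
exhibits the qualitative multi-scanner structure the method targets:
LBP-TOP features (type 3) classify best, histogram-matched intensities
(type 2) clearly but not completely recover the signal, and raw intensities
(type 1) sit at chance — with a one-voxel registration jitter that is what
defeats them. Two design lessons from that calibration are worth recording.
First, with a mild gamma sweep ({0.5, 1, 2}) raw multicenter intensities
remain usable — the between-tissue contrast survives the within-group
gamma variance — so a sweep emulating *wide* acquisition variation is
required for the "unusable type 1" regime. Second, the LBP boundary signal
of a structure whose radius shrink is smaller than the registration jitter
is fragile; target blobs of ~8 voxels radius at one-voxel jitter give a
stable ordering.

**What the phantom does not emulate.** No Rician noise, no bias fields
(beyond the ramp), no partial-volume effects, no nonlinear anatomical
variability between subjects of the same group, no correlation between
scanner assignment and diagnosis. Passing tests on the phantom therefore
show that the implementation realizes the method's assumptions exactly and
behaves as designed *when those assumptions hold*; they do not certify
clinical performance on real multicenter data, where the assumptions are
approximations.

## Histogram matching (type 2)

Classic histogram equalization against a template: within-mask intensities
are mapped through the input's empirical CDF and then the inverse of the
template's CDF, both discretized on 256 bins spanning each mask's own
intensity range (256 matches the 8-bit code range; the bin count was an
open choice and is exposed). The mapping is non-decreasing by construction;
outside-mask voxels are set to 0. Matching a volume to itself reproduces it
up to one bin width, and two gamma variants of the same subject map to
near-identical outputs — up to quantization, which is the precise sense in
which histogram matching "undoes" a global monotone transform. Its
weaknesses on real data (and in the noisy phantom) are that noise moves
mass across bins and that anatomy-dependent histogram differences distort
the mapping — the LBP features avoid both by construction.

## Numerical choices and edge cases

* **Tie convention** $s(0) = 1$: a neighbor equal to the center sets its
  bit, so a constant image codes to 255 everywhere valid. This is the
  standard LBP convention and makes degenerate inputs well defined.
* **Bit order**: ring offsets enumerated clockwise from the top-left of the
  3×3 window, first offset = bit 0. Any fixed order preserves every stated
  property; one is pinned for bit-exact reproducibility against the
  brute-force oracle.
* **Borders**: voxels whose 3×3 neighborhood is incomplete in any of the
  three planes carry code 0 and are excluded via the validity grid rather
  than padded — padding would fabricate neighbors, and brains do not touch
  the grid border after registration.
* **Axis conventions**: with a fixed in-plane offset orientation, swapping
  the volume's first two axes exchanges the sagittal and coronal maps
  exactly (the axial plane transposes, which permutes bit positions); the
  test suite checks the exchangeable pair.
* **Grid tolerance**: spacings are considered equal within 1e-6 mm.
* **Zero-variance voxels, empty selections, all-tied scores**: never
  selected; zero-length feature vectors and majority-class fallback; AUC
  1/2 — all asserted in tests.

## Problem sizes used in tests and the acceptance script

The packaged experiments run at sizes chosen as reasonable desk-scale
defaults: unit tests use 20–32³ grids with 6–24 subjects and 2–5 CV
repeats; the acceptance experiments use the full 64³ grid with 30 subjects
(null calibration, 15 per group) and 40 subjects (multi-scanner comparison,
20 per group, 10-fold CV, 5 repeats). The CV repeat count mainly averages
fold-assignment variance; five repeats are enough for stable mean AUCs at
n = 40, while the 30-repeat default of `cv_config()` matches the protocol
the method prescribes for real cohorts.

## Known limitations

* Rotation-invariant and uniform LBP variants, multi-radius neighborhoods
  and LBP histograms are deliberately out of scope; the method uses plain
  voxelwise codes on affinely registered volumes.
* The t-test is the classical pooled-variance form; no correction, no
  permutation thresholds, no cluster-extent rules.
* Orientation metadata in NIfTI headers is not reconciled; inputs must
  already share a grid.
* The phantom's scanner model is a global monotone transform. Spatially
  varying intensity distortions (bias fields) would break the invariance
  argument locally and are not modeled.
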