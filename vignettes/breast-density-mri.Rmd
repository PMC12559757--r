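---
title: "Volumetric breast density from MRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric breast density from MRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mammographic breast density — the proportion of fibroglandular (dense)
tissue in the breast — is a well-established breast-cancer risk factor, but
in clinical practice it is reported as one of four subjective ordinal
categories (almost entirely fatty, scattered fibroglandular, heterogeneously
dense, extremely dense) with substantial inter-reader variability. Breast
MRI is truly three-dimensional and permits a *quantitative* definition: with
a binary mask of the whole breast, `M_breast`, and of its dense tissue,
`M_dense`, on the same voxel grid,

    breast density = sum(M_dense) / sum(M_breast),

a dimensionless volume fraction in [0, 1]. `mridense` implements the full
computational pipeline around this statistic: DICOM series assembly and
normalization, patch-based volumetric segmentation with a compact 3D V-Net,
the density ratio with contralateral-breast selection, keyword extraction of
report density categories, and the ordinal-continuous concordance analyses
that compare the two modalities.

Because clinical breast MRI with expert dense-tissue annotations cannot be
redistributed, the package ships a synthetic phantom generator that plays the
role of the study cohort. Every stage is exercised end to end on phantoms
with known ground truth; nothing in the package requires patient data.

## The phantom generator: what it emulates, and what it does not

`phantom_spec()`/`generate_phantom()` build a 3D volume in the
left-posterior-superior (LPS) patient convention:

* **Breast geometry.** One or two half-ellipsoids attached to a posterior
  chest-wall plane. Bilateral phantoms have disjoint left/right breasts, so
  laterality splitting has a well-defined truth.
* **Dense tissue.** The upper level set of a smooth Gaussian random field
  (FFT-filtered white noise, correlation length `texture_scale` voxels)
  inside the breast. The level is set per breast side by order statistics, so
  the realized dense/breast voxel ratio matches `target_density` to the
  nearest voxel — far inside the ±0.02 contract the tests check. Thresholding
  a smooth field yields connected, blob-like structures rather than salt-and-
  pepper voxels.
* **Intensities.** Fat-suppressed T1 convention: background ≈ 0, fat ≈ 80,
  dense tissue ≈ 240 (arbitrary units), plus Gaussian noise of SD
  `noise_sd`, quantized to integers in [0, 4095]. The quantization makes the
  16-bit DICOM round trip bit-exact, so series writing and reading can be
  tested as an identity. The bright-dense convention means a classical
  intensity-threshold segmenter is exact on noiseless phantoms and serves as
  the desk-scale oracle for the network.

What phantoms deliberately do **not** model: ducts, vasculature, skin,
bias fields, coil profiles, motion, or vendor DICOM dialects. Passing tests
therefore demonstrate the *correctness of the computational machinery* —
geometry handling, calibration, fusion arithmetic, statistics — not clinical
segmentation accuracy on real anatomy, which requires training on expert
annotations.

## The cohort generator

`cohort_spec()`/`sample_cohort()` draw per-exam demographics and true
densities with the statistical structure the analyses assume:

* Ages uniform over `age_range` (default 20–79).
* True density scaled-beta on [0, 0.8] with mean
  `density_mean + density_age_slope * (age − mid-age)`, clipped to
  [0.005, 0.8]. Defaults: mean 0.11, slope −0.003/yr, dispersion 0.125
  (beta precision 8). These give a right-skewed distribution with most mass
  below 0.2, very little above 0.4, and group SDs that shrink with the mean
  at older ages — the shape reported for real MR density cohorts. The
  linear-mean/scaled-beta law is our generative choice; real cohorts are
  summarized only by group means and SDs, which do not pin down a law.
* Report category = ordinal bin of the true density at
  `category_thresholds` (default 0.04 / 0.10 / 0.20), then shifted one level
  with probability `category_noise` (default 0.1; shifts go inward at the
  scale ends). This emulates radiologist report variability; the value is a
  free parameter of the generator, not an estimate of real inter-reader
  disagreement. Report sentences are rendered from templates that embed the
  exact keyword phrases the mapper searches for, so generator and mapper
  share one vocabulary table and noise-free cohorts round-trip exactly.
* The lower clip at 0.005 avoids phantoms whose dense region would vanish;
  the upper clip at 0.8 keeps the beta mean parameterization valid.

## DICOM handling

No DICOM toolkit is declared as a dependency: the package contains a minimal
single-frame MR reader/writer restricted to Explicit VR Little Endian and
the standard tags (positions, orientation, spacing, pixel data, patient
metadata). The reader sorts slices by ImagePositionPatient projected onto
the slice normal — not by InstanceNumber — and therefore loads series written
superior-first (descending z) identically to inferior-first ones; the
detected file order is reported. Mixed series in one directory and slices
with missing position tags are errors, never silent merges. Multi-frame
(enhanced) DICOM and vendor private tags are out of scope. One test
cross-checks the writer against pydicom as an independent reader.

`zscore_normalize()` standardizes a volume to mean 0, SD 1 over *all*
voxels, background included. Whole-volume statistics are a deliberate,
documented choice so that training and inference agree; a constant volume is
an error.

## Patch-based segmentation

Inference runs on a grid of fixed-size sub-volumes (default 96³ stepped
8 × 8 × 3 along x/y/z): per axis, `steps` start indices are uniformly spaced
in real arithmetic from 0 to `dim − patch`, rounded to integers, and
deduplicated. "Uniform steps" is read as the number of start positions per
axis; full voxel coverage is verified and violating it is an error.
Overlapping probability blocks are fused by equal-weight averaging (each
voxel's value is the arithmetic mean of all patches covering it), counts are
recorded, and the fused volume is binarized at threshold 0.5 by default (the
binarization level is our choice). Volumes smaller than the patch are
zero-padded symmetrically and cropped after fusion. A voxel covered by no
patch is an error that names the voxel.

The segmenter is a compact 3D V-Net: residual stage blocks (3³ volumetric
convolution + ReLU, plus a 1³ linear projection of the block input), strided
2³ convolutions for downsampling with channel doubling, nearest-neighbour
upsampling followed by 3³ convolution with additive skip connections on the
way up, and a 1³ sigmoid head. Convolution forward/backward passes are C++
kernels; everything runs single-threaded and deterministically under the
config seed. Dense-tissue masks are intersected with the breast mask after
prediction so the density ratio's containment precondition holds by
construction.

**Loss.** Soft Dice is the architecture's native objective and the default.
On phantoms the foreground is rare (a few percent of voxels), and pure Dice
optimization from random initialization can collapse into the all-background
local optimum at aggressive learning rates. The `"dice+ce"` option adds a
voxel-mean cross-entropy term that removes this failure mode; the package's
own training runs (tests, acceptance script) use it with Adam at lr 0.03.

**Problem sizes.** The package's training demonstrations use the tiny
configuration — base 4 channels, depth 2, 48³ patches, 20 phantoms, 6 epochs
(120 iterations) — chosen so a laptop-class CPU trains a model in about a
minute while still reaching held-out Dice ≥ 0.85 on noiseless phantoms and
≥ 0.95 when overfitting a single phantom. These runs demonstrate that the
architecture, gradients and training loop are correct, not that the model
is clinically adequate; clinical-scale training data and trained weights are
out of scope.

**Metrics.** `dice_coefficient()` is `2|A∩B|/(|A|+|B|)` (1.0 when both
masks are empty); `hausdorff_distance()` is the exact symmetric Hausdorff
distance between foreground voxel-center point sets (no percentile
variant), in voxel units by default with an optional physical spacing. Both
are validated against brute-force oracles.

## Density, laterality, and the contralateral rule

`compute_density()` is exact voxel counting with strict preconditions
(non-empty breast, dense ⊆ breast). `split_laterality()` partitions a
breast mask into left/right: 6-connected components first (components are
assigned by centroid x, anchored by the two largest), with a fallback split
at the volume's mid-coronal plane for a single component spanning the
midline; larger x is the patient's left under LPS. In exams with a known
cancer side only the contralateral normal breast is reported. For screening
exams (no cancer) no convention is universal; the package reports both
sides and uses their mean as the exam-level value, configurable to
left/right/max.

## Report mapping

`classify_report_text()` does case-insensitive substring matching against an
editable keyword table, evaluated from the densest category down; the first
match wins, a multi-level match (e.g. a report quoting the prior exam) warns
and keeps the highest level, and a text with no key phrase is explicitly
unclassifiable (`NA`), never silently defaulted. Internal whitespace runs
are collapsed before matching. Negation is *not* parsed: "not extremely
dense" matches "extremely dense" — a documented limitation shared with the
keyword approach generally. Only the standard printed phrases ship in the
table; site-specific phrasing is an explicit extension via the table.

## Concordance and the ordinal classifier

`concordance()` computes tie-corrected Spearman rho (Pearson correlation of
midranks; two-sided p from the large-sample t approximation) and Kendall
tau-b — the tie-corrected variant, appropriate because category data are
heavily tied — with the standard tie-corrected normal approximation for its
p-value. Both are cross-checked against first-principles oracles in tests.

The "density-only classifier" experiment is implemented as an ordinal
threshold classifier: three ascending cut-points maximizing 4-class training
accuracy, found exactly by dynamic programming over cut positions of the
sorted densities. Any monotone single-feature classifier (including a linear
SVM on one feature) realizes exactly this decision structure, so the
exhaustive search gives the optimum of the whole family deterministically,
with no margin-solver dependence. The 80/20 train/test split is stratified
by category under a fixed seed. The binary AUC between "scattered" and
"heterogeneously dense" is the rank-based pair probability (ties counted
1/2), computed on the two classes only.

## Numerical and degenerate-input choices

* Phantom dense calibration by order statistics (exact to one voxel) rather
  than iterative threshold bisection; ties at the cut are trimmed
  deterministically.
* Density clipping to [0.005, 0.8]; infeasible targets (dense region under
  one voxel) are errors rather than silent rounding.
* Z-scores over whole volumes; constant volumes are errors.
* Patch-grid start rounding: nearest integer on the real uniform spacing,
  then deduplication.
* Spearman p-values: t approximation (adequate at the n ≥ 10 precondition);
  all-tied categories are an error, as the correlation is undefined.
* The classifier's threshold ties resolve to the smallest cut indices, so
  fits are reproducible under row reordering of equal-density data.
* All seeds are explicit; identical specs and seeds reproduce phantoms,
  cohorts, training trajectories and pipeline outputs bit-identically
  (modulo floating-point formatting in JSON).

## Known limitations

* Phantoms are geometric, not anatomical; results on them bound nothing
  about clinical accuracy.
* The DICOM layer reads only the dialect it writes (plus standard
  conforming single-frame explicit-LE series); enhanced multi-frame objects
  and implicit VR are rejected with clear errors.
* Report mapping is keyword-based; negation and free-text nuance are out of
  scope.
* The screening-exam density convention (mean of sides) is a package
  choice; per-breast analyses remain available via the per-side rows.
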