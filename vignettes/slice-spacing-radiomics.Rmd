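---
title: "Slice-spacing-aware radiomics: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-spacing-aware radiomics: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sliceomics)
```

## The scientific question

Chromosomal 1p/19q co-deletion is a diagnostic, prognostic and predictive
biomarker in lower-grade glioma (LGG), normally determined by FISH on tumor
tissue. Radiomics signatures — machine-learning models over high-throughput
quantitative image descriptors of a tumor region of interest (ROI) — can
predict the co-deletion status non-invasively from MRI. Clinical MR series,
however, vary widely in inter-slice spacing (from sub-millimetre
"thin-slice" 3D acquisitions to 5–6 mm conventional series), and texture
descriptors defined over adjacent-voxel neighbourhoods are sensitive to that
geometry. `sliceomics` implements, end to end, the experiment that isolates
this effect: build one signature from thin-slice contrast-enhanced T1
(CE-T1) plus T2 features, build a second from a *simulated-conventional*
(SC) CE-T1 series — the same thin series with only one of every five slices
retained — plus the same T2 features, and compare the two with the paired
DeLong test.

Because no patient imaging is distributed with the package, a seedable
synthetic cohort generator supplies volumes with the statistical structure
the analysis assumes; every stage is exercised and tested against it.

## The synthetic cohort: what it emulates

`cohort_config()` defaults describe a 96-case LGG cohort: ~22.9% 1p/19q
co-deleted, 78/96 training fraction, ~65.6% IDH-mutant (every co-deleted
case is IDH-mutant, as in the 2016 WHO classification), ~46.9% WHO grade
III. Each case carries:

* a thin-slice CE-T1-like series on a 0.5 mm isotropic grid,
* a thick-slice T2-like series sharing the physical extent at 6 mm
  through-plane spacing (generated pre-aligned, standing in for the
  coregistration a clinical pipeline would perform),
* a contiguous ellipsoidal tumor ROI rendered on both grids, and
* FISH probe ratios consistent with the label under the strict `< 0.75`
  arm-loss rule (`fish_call()`), including a ~9% fraction of single-arm-loss
  cases among the intact class.

Two class-dependent mechanisms carry the predictive signal:

1. **Texture**: within the ROI the intensity is a Gaussian random field —
   white noise smoothed with an axis-wise Gaussian kernel — rescaled to unit
   variance, plus independent voxel noise (`noise_sd`, default 0.8).
   Rescaling to unit variance means the classes differ in *correlation
   structure only*, not in first-order marginals, so the planted signal
   lives where the clinically selected features live (GLCM Correlation /
   IMC2, GLDM Dependence Entropy). The in-plane kernel width is 0.5 mm with
   a per-case jitter of ±0.3 mm; the through-plane width is 0.35 mm with an
   *independent* ±0.15 mm jitter; co-deleted cases gain
   `0.5 × texture_effect` (default 0.4 mm) on each component. Two details
   are load-bearing. First, because the two components are jittered
   independently, the through-plane correlation carries class information
   that in-plane texture cannot substitute — without this, a thick-interval
   series could recover the entire class signal from in-plane voxel pairs
   and no thin-slice advantage would exist. Second, the through-plane width
   stays in the 0.35–0.6 mm range: wide enough that 0.5 mm-spaced neighbours
   resolve the class difference, narrow enough that at the 2.5 mm SC
   interval the correlation is effectively zero *for both classes*, so
   slice retention genuinely destroys that component rather than merely
   attenuating it. Under these conditions the default cohort reproduces the
   thin-versus-thick operating point of its clinical counterpart (replicate
   mean validation AUC ≈ 0.93 for the 3D signature vs ≈ 0.81 for SC).
2. **Shape**: ellipsoid axis ratios are drawn with a co-deletion shift
   (`shape_effect`, default 0.15) at class-independent volume, making major
   axis length and elongation informative without confounding by size.

Effect sizes were calibrated so that a default cohort lands at the operating
point clinical cohorts of this size show (validation AUC roughly 0.85–0.95
for the thin-slice signature, ~0.1 lower for SC), with genuine class
overlap; with both effects at 0 the classes are exchangeable and validation
AUC centers on 0.5. The default grid is 40×40×32 voxels — a desk-scale stand-in
for 512×512 clinical matrices, chosen so a 96-case experiment runs in tens
of seconds; the ROI still spans thousands of voxels, so texture estimators
are in a realistic regime.

What the generator does *not* emulate: scanner noise spectra and bias
fields, infiltrative tumor margins, necrosis or cysts, inter-sequence
misregistration, and anatomical background. Passing tests therefore
demonstrate internal correctness and the slice-spacing mechanism under
controlled conditions, not clinical performance.

## Geometry and preprocessing conventions

* Axis order is (x, y, z) with z through-plane; voxel indices are 0-based in
  geometry computations; spacing is mm per axis. NIfTI I/O (`read_volume`,
  `write_volume`) stores spacing in `pixdim` and the origin in the
  sform/qform translation.
* `normalize_volume()` centers at the whole-volume mean and scales to SD
  `scale` over **all** voxels, not only the ROI. The default `scale = 1`
  gives the textbook mean-0/SD-1 contract; the pipeline uses `scale = 100`
  so that the default texture bin width of 25 resolves about a quarter of an
  intensity SD (with SD-1 intensities a width-25 bin would collapse the ROI
  to a single gray level).
* `interpolate_inplane()` is bilinear with pixel-center alignment; in-plane
  spacing scales by source/target, the through-plane axis is untouched.
* `downsample_to_sc()` retains slices `phase, phase + k, phase + 2k, ...`
  (default `k = 5`): retained slices are bit-identical copies — no
  averaging, which would blur and introduce partial-volume effects — the
  through-plane spacing is multiplied by `k`, the origin shifted by `phase`
  source spacings, and `ceiling((N - phase)/k)` slices survive. The `phase`
  parameter (the choice of interleave, which published protocols leave
  unstated) makes the location
  dependence of re-sampling testable. Order of operations in the pipeline:
  down-sample first, then normalize each series independently (the
  alternative order is not distinguishable from the published description;
  this one treats the SC series as an independent acquisition, which is what
  it simulates).
* `consensus_roi()` measures inter-rater disagreement as the Jaccard
  distance |A△B|/|A∪B| (the published rule names a "difference" without
  defining it; the symmetric, bounded choice matches the "overlapping area"
  remedy) and returns the intersection when it is ≤ 5%, otherwise flags
  arbitration.

## The 107-feature extractor

`extract_all()` computes 14 shape, 18 first-order, 24 GLCM, 16 GLRLM, 16
GLSZM, 14 GLDM and 5 NGTDM features. Conventions that matter:

* **Discretization** (`discretize()`): fixed bin width, min-anchored floor
  rule `level = floor((v − min)/w) + 1` — texture is invariant to intensity
  shifts by construction. Default `w = 25` on scale-100 normalized
  intensities; both knobs are explicit arguments so conformance deviations
  against other extractors are traceable.
* **Neighbourhoods**: all texture families use distance-1 neighbours on the
  voxel lattice with *no* mm correction. This is deliberate and is precisely
  why SC features diverge from thin-slice features — after slice retention a
  "adjacent" voxel pair spans 2.5 mm through-plane instead of 0.5 mm. Shape
  features, by contrast, always work in physical mm.
* **Aggregation**: GLCM and GLRLM build one matrix per direction over the 13
  unique 3D offsets; GLCM matrices are symmetrized and normalized per
  direction; feature values are averaged across directions (directions
  contributing no pairs are skipped). GLSZM uses 26-connected constant-level
  zones; GLDM counts 26-neighbours with level difference ≤ α (default 0),
  dependence excluding the center voxel, matrix column = dependence + 1;
  NGTDM uses the in-ROI 26-neighbourhood mean, voxels with no valid
  neighbour excluded.
* **Degenerate single-level ROI**: Correlation := 1, IMC1 := 0, IMC2 := 0,
  MCC := 1, entropies 0; the feature vector carries a `degenerate`
  attribute. This keeps the extractor total on pathological inputs.
* **Mesh geometry**: surface area and mesh volume come from a marching-
  tetrahedra iso-surface (six tetrahedra per grid cube, level 0.5) of a
  lightly smoothed mask field (Gaussian, σ = 0.8 voxel). The smoothing
  suppresses the voxelization jaggedness that would otherwise inflate the
  area of a digitized ball by ~30%; with it, a radius-10 ball has sphericity
  0.99. Thin structures whose smoothed interior drops below the iso-level
  fall back to the raw binary mask. Principal axis lengths are
  4·√(eigenvalue) of the spacing-weighted coordinate covariance (population
  form); maximum 2D/3D diameters are brute-force pairwise distances over
  surface voxels, per axial/coronal/sagittal plane family for the 2D
  variants.

Every texture matrix is verified, over hundreds of random small ROIs,
against independent brute-force enumerations (explicit pair loops, `rle`
over extracted lattice lines, iterative zone growing) that share no code
with the Rcpp kernels.

## Signature construction

Features from two modalities are concatenated (3D signature: thin CE-T1 +
T2; SC signature: SC CE-T1 + T2, *de novo* selection for each) and the
training table alone drives every fitted quantity:

1. **Scaling** — each feature divided by its training-set SD
   (`scale_features()`); validation rows are scaled with the *training* SDs.
   Constant features are dropped with a warning.
2. **LASSO** (`lasso_select()`) — L1-penalized logistic regression
   (`glmnet`), penalty chosen by 5-fold cross-validated deviance with a
   seeded fold assignment. Default rule is minimum CV deviance; the 1-SE
   rule is available. Selected features are returned ordered by
   |coefficient|.
3. **Random forest** (`fit_signature()`) — 500 trees, √p candidates per
   split, seeded. One feature-reduction pass drops features with unscaled
   out-of-bag permutation importance ≤ 0 and refits once (the published
   protocol allows "feature reduction at this step" without specifying the
   rule; importance ≤ 0 is the smallest defensible criterion). If LASSO
   selects nothing (possible under null effects), the pipeline falls back to
   a constant prevalence predictor rather than failing.
4. **Classification threshold** 0.5 for accuracy/sensitivity/specificity;
   co-deletion is the positive class throughout; the ~22% class imbalance is
   left unweighted, matching the apparent clinical protocol.

A leakage guard is asserted in the test suite: building the signature with
validation rows entirely withheld produces byte-identical scaler, selection,
forest and training predictions.

## Evaluation

`auc_midrank()` is the tie-aware Mann–Whitney AUC. `delong_test()` compares
two correlated ROC curves via placement-value (structural-component)
covariance: z = (AUC₁ − AUC₂)/√(v₁ + v₂ − 2c), two-sided normal p-value;
`delong_ci()` gives 95% CIs as AUC ± 1.96·SE. CI bounds are truncated to
[0, 1] for reporting (reproducing the "x.xxx–1.000" convention of clinical
tables) with raw bounds retained. Identical score vectors yield p = 1 rather
than 0/0. The implementation is cross-checked in the tests against `pROC`'s
DeLong routine to ~1e-9 and against a bootstrap variance oracle, and its
null calibration (type-I error at α = 0.05 within [0.03, 0.07] over 500
simulated paired null datasets at the training-set composition 16+/62−) is
part of the acceptance suite. `evaluate_subgroups()` re-applies fixed
predictions inside IDH-mutant and WHO-grade subsets without refitting;
single-class subgroups get a flagged, undefined AUC.

## Occlusion maps

`occlusion_map()` veils a 5×5 in-plane patch (stride 5) at each grid
position of the ROI bounding box on each slice, overwrites it with a fill
value, re-extracts one named feature over the unchanged ROI and records the
change. Open choices are explicit config: "black" fill defaults to the
volume minimum; the contribution score defaults to |Δf| (signed and relative
variants available); positions whose patch misses the ROI score 0; the ROI
mask itself is never altered, so pure shape features yield identically zero
maps — a useful negative control. `compare_occlusion()` aligns an SC map's
slices back to their thin-series sources (SC slice k ↔ thin slice
(k−1)·keep_every + phase + 1) and summarizes per-position differences by
mean |Δ| and Spearman rank correlation.

## Orchestration and problem sizes

`run_experiment()` runs generate → split → down-sample → normalize →
extract (3 modalities × 107 features) → build both signatures → evaluate →
DeLong-compare → subgroup re-evaluation (→ optional occlusion maps), fully
reproducible from the config: the cohort seed drives generation and the
split/LASSO/forest seeds default to cohort seed + 1/2/3.
`replicate_experiment()` derives per-replicate cohort seeds from the master
seed and aggregates metrics across independent cohorts.

Problem sizes used in the shipped tests and acceptance script are the
package's own choices for a desk-scale study: 96-case cohorts on 40×40×32
grids for the headline experiment, 20 replicates for the ordering and
signal-recovery properties, 24–36-case cohorts on 28×28×22 grids for
orchestration and monotonicity checks, 500 null simulations for DeLong
calibration and 2000 bootstrap resamples for the variance cross-check.

## Known limitations

* The generator's ellipsoidal, texture-stationary tumors are a deliberately
  minimal model; none of the results here certify performance on clinical
  images.
* Texture features use lattice neighbourhoods without isotropic resampling;
  extractors that resample to isotropic voxels first will disagree on
  anisotropic grids by design.
* Wavelet/filtered feature banks and 2D-only extraction modes are out of
  scope, as are DICOM ingestion, deformable registration and skull
  stripping.
* The forest's in-sample (training) probabilities are nearly separable on
  signal-bearing cohorts, so training AUCs saturate near 1; validation
  metrics and replicate means are the meaningful quantities.
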