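---
title: "PET radiomics survival prediction: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PET radiomics survival prediction: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`fetrad` implements a complete radiomics survival-prediction pipeline for
static amino-acid PET imaging of brain tumors: tumor-to-background-ratio
(TBR) threshold segmentation, fixed-bin-width intensity discretization, a
107-feature radiomics engine, PCA-based construction of four feature
datasets, univariate Cox and Kaplan-Meier screening, and random-forest
classification (one-year survival) and regression (survival days) evaluated
under cross-scanner testing scenarios. Because clinical PET cohorts of this
kind are not publicly releasable, the package ships a synthetic phantom
generator whose cohorts carry a planted, proportional-hazards survival
signal; the pipeline is exercised and validated end-to-end on those
phantoms.

# The phantom generator

## What it emulates

Each subject is an ellipsoidal lesion (semi-axes $a \ge b \ge c$, random
orientation) on a background normalized to TBR $= 1$. Lesion uptake either
is flat at `peak_tbr` or falls off linearly from `peak_tbr` at the centre to
1 at the boundary; cohort sampling uses the linear profile, which produces
genuinely different VOIs at the 1.4 / 1.6 / 1.8 thresholds the way real
uptake gradients do. Intratumoral heterogeneity is a multiplicative
Gaussian random field (spectrally shaped by Gaussian filtering of white
noise) with a controllable amplitude and correlation length. Two scanner
profiles reproduce the reproducibility question the pipeline is designed to
probe:

* `osem2d`: 2.035 x 2.035 x 2.425 mm voxels, no post-filter, background
  noise CV 0.10 — the homogeneous "training" scanner;
* `osem3d`: 1.018 x 1.018 x 2.027 mm voxels, 5 mm Gaussian
  post-reconstruction filter, noise CV 0.15 — the newer "testing" scanner.

The grid shapes default to desk-scale crops (~145 mm field of view) rather
than full clinical matrices; all tests and the bundled analyses state the
grids they use. The planning-target-volume (PTV) surrogate is the true
tumor support dilated by a 20 mm margin (morphological dilation with a
spherical element, emulating the clinical target-volume margin convention),
optionally minus an exclusion mask — so the PTV is much larger than the
metabolically active tumor, as in treatment planning.

Noise is multiplicative Gaussian on the smooth activity map, not a
sinogram-level reconstruction simulation. This is sufficient to create
scanner-profile-dependent feature shifts (spacing, post-filter, noise
level), which is the property the cross-scanner scenarios need; it does not
reproduce reconstruction artifacts, partial-volume bias at air/bone
interfaces, or dynamic-frame kinetics. Consequently, passing tests show
that the *pipeline* behaves correctly and that planted geometric effects
survive a scanner change — they do not certify clinical performance.

## The survival link

Event times are exponential with hazard
$h = h_0 \exp\{\sum_i \beta_i (x_i - m_i)\}$ over ground-truth covariates
(by default the physical major axis length $2a$ in mm, centred at 42 mm),
with every subject experiencing the event (complete follow-up), matching a
high-grade tumor cohort; administrative censoring is available but off by
default. The default slope is $\beta = 0.10$ per mm with
$h_0 = 1/450$ days$^{-1}$. The slope was fixed at design time by a power
analysis: with the default size range (major axis 24–60 mm), exponential
times make one-year status intrinsically noisy, and a slope of 0.05/mm
caps the *Bayes-optimal* classification AUC at about 0.71 — too weak a
planted signal to distinguish a working pipeline from a broken one. At
0.10/mm the ideal AUC is about 0.85 and the one-year prevalence about
0.43, an unambiguous but not trivial effect, mirroring a clearly
significant clinical size effect. The one-year label is `time >= 365`
days.

# Segmentation

The TBR map is the image divided by a background level estimated either
from an explicit healthy-tissue mask (phantoms emit one: the PTV
complement) or from a spherical shell around a reference point — a
deterministic, scriptable analogue of semi-automatic background regions
drawn in clinical tools. A VOI at threshold $t$ is the 26-connected
component of $\{TBR \ge t\}$ containing the seed point (the true tumor
centre in phantom work); a seed below threshold is relocated to the nearest
above-threshold voxel within a configurable search radius (30 mm default).
Empty results raise a classed condition (`fetrad_empty_voi`) and, at the
cohort level, drop that subject from the affected VOI's feature table with
a warning rather than aborting a whole evaluation — small lesions on the
smoothed scanner profile can genuinely lose their TBR-1.8 core.

# Discretization and the feature engine

Intensities inside a VOI are discretized with a fixed bin width; the width
is the mean voi14 TBR range of the *training* subjects divided by 64 bins,
computed once and frozen for every other VOI and for test subjects (the
bundled planted-signal analysis calibrates it on its initial 25-subject
training chunk, mirroring the clinical convention of deriving the width
from the initial homogeneous cohort). Three
anchoring conventions are implemented: `voi_minimum` (default;
`floor((v - min)/W) + 1`), `grid_aligned` (bin edges at integer multiples
of the width — the convention of the reference extraction software, used
when cross-validating against it), and `zero`. Under `voi_minimum`, adding
a constant to all VOI intensities leaves every texture feature unchanged;
under `grid_aligned`, level *values* can shift by a constant, which
affects only gray-level-weighted features.

The 107 features comprise 18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16
GLSZM, 5 NGTDM and 14 GLDM features with IBSI-aligned definitions.
Conventions that the field leaves open were fixed as follows and are
asserted by tests:

* GLCM and GLRLM are computed per direction over the 13 unique offsets at
  Chebyshev distance 1 and the *feature values* averaged over directions
  (a `merged` mode that sums matrices first is also available); GLCM
  slices are symmetrized; gray-level weights use the actual discretized
  level values, not re-indexed ranks.
* GLSZM zones are 26-connected equal-level components; NGTDM and GLDM use
  the full 26-neighbourhood; GLDM dependence (with tolerance
  $\alpha = 0$) counts the centre voxel, so sizes start at 1.
* Degenerate VOIs never produce missing values: a constant VOI has
  entropy 0, uniformity 1, skewness/kurtosis 0; a single-voxel mask has
  axis lengths 0 and elongation/flatness 1; GLCMs without any voxel pair
  fall back to documented feature defaults.
* First-order moments are population moments; kurtosis is not
  excess-corrected.

Shape axes come from the eigenvalues $\lambda_1 \ge \lambda_2 \ge
\lambda_3$ of the covariance of the physical voxel-centre coordinates:
major axis length $= 4\sqrt{\lambda_1}$, elongation
$= \sqrt{\lambda_2/\lambda_1}$ (1 for a sphere, tending to 0 for a line),
flatness $= \sqrt{\lambda_3/\lambda_1}$. For a uniform solid ellipsoid
$\lambda_1 = a^2/5$, so the feature equals $4a/\sqrt{5} \approx 1.79a$;
tests validate against this exact solid-ellipsoid oracle, while the
phantom's *truth map* reports the physical extent $2a$ as the planted
covariate (that is the quantity a planted size effect acts on, and the
`Maximum3DDiameter` feature estimates it directly).

The surface mesh is extracted by marching tetrahedra (Kuhn 6-tetrahedron
cube subdivision of the zero-padded binary mask, iso-level 0.5). The
subdivision is face-compatible across cubes, so the mesh is closed and
orientable; mesh volume agrees with classic marching cubes to well under
0.1%. Surface *area*, however, is systematically larger than the classic
marching-cubes value on smooth shapes (about 15–20% on digitized balls)
because the tetrahedral tessellation adds ridge vertices at face and cube
centres; this bias is stable and affects `SurfaceArea`,
`SurfaceVolumeRatio` and `Sphericity` consistently across subjects (the
three are the only features that differ by more than 1% from the
independent reference oracle). Diameter features are computed from the
cube-edge iso-crossing vertices only (the canonical marching-cubes vertex
positions), so they agree with the reference convention; beyond 4000
vertices the exact pairwise maximum switches to directional-extreme
candidates over 250 deterministic sphere directions, exact for the
convex-ish vertex clouds that occur in practice.

## Cross-implementation validation

Because the standard extraction package is a Python tool, the engine is
validated two ways: (i) every texture-matrix builder is compared
entry-by-entry against brute-force enumeration on random small grids, and
(ii) the full 107-feature vector is compared against a frozen output of an
independently written Python oracle (`tools/reference_features_oracle.py`,
numpy/scipy/scikit-image; marching cubes from scikit-image) evaluated on
the deterministic digital phantom returned by `digital_phantom()`. The
frozen values live in `inst/extdata/digital_phantom_oracle_features.csv`;
at least 95% of features must agree within 1% relative difference, and in
the current build 104 of 107 do (the three exceptions are the
surface-area-derived features discussed above).

# Dimensionality reduction and the four datasets

Features are standardized to zero mean and unit population variance using
training-subject statistics only (zero-variance features map to 0 with a
warning). PCA is computed by SVD of the centred standardized matrix;
explained-variance ratios are normalized squared singular values, and the
retained dimension is the smallest $k$ whose cumulative ratio reaches the
variance target (default 0.95, within the conventional 0.90–0.95 band).
The four datasets are: **Top** (for each retained component, the 10
features of largest absolute loading; union over components, deduplicated,
ties at the cutoff broken by feature-name order), **PC** (retained
component scores of the 107-feature set), **SH-FO** (the 32 shape +
first-order features), and **PC(SH-FO)** (component scores of a PCA
refitted on the 32). "Highest loadings" is interpreted as largest
absolute loading, and duplicated Top features are kept once, since the
dataset feeds models on feature values. A per-feature selection indicator
supports selection-frequency summaries across the four VOIs.

# Survival models

Univariate Cox fits use the partial likelihood with Efron tie handling
(via the `survival` package); the Wald p-value at the 5% level flags
relevant features, with no multiplicity correction by default (a
Benjamini–Hochberg option exists). Non-converged or degenerate fits are
flagged and never counted significant. Kaplan–Meier stratification splits
at the feature median (ties to the lower group) and compares groups by the
two-sample log-rank test.

Random forests (via `ranger`, single-threaded for reproducibility) handle
classification of one-year survival — scored by AUC, computed as the
normalized Mann–Whitney statistic — and regression of survival days —
scored by the concordance index over comparable pairs (with complete
follow-up every pair with distinct times is comparable; prediction ties
count one half). Class weights default to "balanced". Hyperparameters
(trees, minimum node size, features per split) are tuned by a
coarse-to-fine randomized search: stage 1 samples settings log-uniformly
from broad ranges; stage 2 resamples within a multiplicative window (x2 by
default) around the stage-1 winner. One fold assignment is shared by the
whole search and forest seeds are keyed on setting values, so re-evaluating
a setting reproduces its score exactly and the refined stage — which
re-includes the stage-1 winner — can never score worse. Defaults: 50
sampled settings per stage and 5 inner folds for standalone use; the
bundled evaluation configurations use smaller budgets (stated where used)
because the phantom cohorts are small.

# Evaluation scenarios and leakage policy

Two scenarios mirror the cross-scanner design: **independent** (train on
all `osem2d` subjects, test on all `osem3d` subjects) and **combined_cv**
(5-fold cross-validation over the pooled cohort). Every quantity with
fitting character — bin width, standardizer, PCA, Top selection, forest
hyperparameters — is fitted on the training portion only; in combined CV
the entire stack is refitted inside each fold (strict nesting, chosen to
avoid optimistic bias) and cell values are averaged over folds. Reports
cover the full VOI x dataset-variant x task grid; cells above 0.65 are
flagged, and failed cells (e.g. a single-class test fold) carry an
explanatory note instead of a value. Tests assert that corrupting
test-set survival changes neither chosen hyperparameters nor predictions.

# Numerical choices and degenerate inputs

* Logarithms in entropy-like features add machine epsilon, matching the
  numpy convention of the reference software.
* Component labelling uses graph components (via `igraph`) on the voxel
  adjacency of the 26-neighbourhood.
* Dilation uses FFT convolution with a spherical element on the tumor
  bounding box (padded to 5-smooth sizes), thresholded at half a voxel.
* The Gaussian post-filter and the texture field use separable
  edge-replicating convolution, truncated at 4 sigma.
* All randomness flows from explicit integer seeds; child seeds are
  derived arithmetically (32-bit safe) per stage, so identical
  configurations reproduce cohorts, searches and reports bit-for-bit.

# Problem sizes used by the bundled analyses

The test suite and the reproduction script run entirely on synthetic
phantoms at stated sizes: module tests use grids around 36–56 voxels per
axis; the structural checks build the 25 + 12 two-scanner cohort on 60^3
(coarse profile) and 116 x 116 x 56 (fine profile) grids; the
planted-signal analysis uses 150 training and 80 test subjects at those
same grids with the default tumor and link settings. These sizes are the
package's chosen desk-scale study conditions; the generator accepts full
clinical matrices (128 x 128 x 63 and 336 x 336 x 109) unchanged.

# Known limitations

* No sinogram/OSEM reconstruction, no dynamic frames, no MRI surrogate;
  scanner differences are emulated at the image level.
* No wavelet- or Laplacian-filtered feature maps, no isotropic resampling,
  no 2D slice-wise extraction.
* Surface-area-derived shape features carry the marching-tetrahedra bias
  described above; they are internally consistent but not interchangeable
  with classic-marching-cubes values.
* The exact geometry of crescent-shaped contralateral background regions
  used in clinical practice is not reproduced; background estimation is
  configurable (explicit mask or spherical shell).
* Univariate Cox screening is restricted to the Top datasets by design;
  multivariate Cox is deliberately out of scope for cohorts of this size.
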