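---
title: "Regional radiomics with a sparse-representation classifier: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional radiomics with a sparse-representation classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`srcradiomics` implements a complete regional-radiomics classification
pipeline for multimodal 3-D brain MRI: a seeded synthetic cohort generator
with a cerebellar-style 26-region parcellation, a 57-feature radiomic
catalogue computed per region and modality, sparse-coding feature screening,
a sparse-representation classifier (SRC) solved by orthogonal matching
pursuit (OMP), and a stratified cross-validation/test evaluation protocol
with confusion-matrix metrics and ROC/AUC. This vignette is the package's
account of the underlying methods, the design decisions that were genuinely
open, and what the synthetic experiments do and do not demonstrate.

## The synthetic cohort generator

Real diagnostic cohorts of this kind (healthy controls, mild cognitive
impairment, Alzheimer's disease, each scanned with T1-, T2- and
T2-FLAIR-weighted sequences and parcellated into 26 cerebellar regions) are
rarely redistributable, so the package ships a phantom generator whose
output has the same shape as the real inputs: per-subject co-registered 3-D
volumes, one integer label map shared across the cohort, and a manifest CSV.

The generator's model is deliberately minimal. The label map is an
ellipsoidal foreground (semi-axes 45% of each grid dimension) partitioned by
nearest-seed (Voronoi) assignment from seed points drawn uniformly inside
the foreground; parcels are therefore contiguous, cover the foreground
exactly, and every label in `1..n_regions` occurs. Layouts leaving a parcel
under 50 voxels are redrawn deterministically; a grid that cannot give every
parcel 50 voxels is rejected with a sizing error.

Each modality volume of a subject in group $g$ is

$$ v = \mathrm{gain}_m \cdot \big( b + \mu_g + \varepsilon_g \big), $$

where $b = 100$ is a constant baseline, $\mu_g$ the group's additive mean
shift, and $\varepsilon_g$ white Gaussian noise smoothed by an isotropic
Gaussian kernel of standard deviation $s_g$ voxels (separable convolution,
truncated at $3\sigma$, boundary-renormalized) and rescaled to marginal
standard deviation $\sigma_g$. The smoothing scale is the texture knob:
larger $s_g$ means a longer spatial correlation length, which monotonically
lowers gray-level co-occurrence contrast and related texture features, so
both intensity and texture carry group information through a single
parameter each.

Defaults encode the study conditions used throughout the tests: 30 subjects
per group on a $64 \times 64 \times 32$ grid, mean shifts $(0, 1, 2)$ noise
standard deviations for (HC, MCI, AD), smoothness $(1, 1.25, 1.5)$ voxels
(a 1.5-fold contrast between the extreme groups), unit noise SD, and
modality gains $(1, 0.9, 1.1)$. Master seed 20240101; subject $i$ uses seed
`master + i`, recorded in the manifest, so cohorts regenerate
voxel-identically.

What the generator does *not* emulate: anatomy (no skull, no
tissue classes), MRI physics (no bias fields, no k-space artifacts, no
anisotropic voxels even though clinical slice thicknesses differ per
sequence), registration error (the label map is shared exactly), site
effects, and any group difference in region *shape* or *volume*. Passing
recovery tests on these phantoms therefore demonstrates that the pipeline
is correct and leak-free, not that the classifier would reach comparable
accuracy on clinical scans.

## Quantization and the 57-feature catalogue

Matrix-based texture features need discrete gray levels. Each region is
quantized independently with equal-width bins between its own minimum and
maximum (32 levels by default, configurable); ties at the maximum go to the
top level, and a constant region maps to level 1 and is flagged. Because
binning is min–max relative, every quantized-domain feature is invariant to
positive affine rescaling of the input intensities — a property the test
suite asserts. The number of levels trades sensitivity against sparsity of
the count matrices; 32 is the common default of published radiomics
toolkits, and no claim in the package depends on it.

Per (region, modality) the catalogue has 57 features in a fixed order:

* **18 intensity features.** Twelve are statistics of the native voxel
  intensities (energy, min/max/range, mean, median, mean absolute
  deviation, RMS, variance, SD, skewness, kurtosis) using the population
  ($1/n$) moment convention with non-excess kurtosis — conventions differ
  across software, so they are pinned here and verified against Monte-Carlo
  values in the tests. Six `h-` features are computed on the normalized
  histogram of quantized levels: `h-Mean`, `h-Variance`, `h-Skewness`,
  `h-Kurtosis` (moments of the level distribution), `h-Uniformity`
  $\sum_i p_i^2$, and `h-Energy`, defined here as the second raw moment
  $\sum_i p_i\, i^2$ (the catalogue names both an energy and a uniformity;
  making `h-Energy` the raw second moment keeps the two distinct and both
  well defined on a constant region).

* **8 GLCM features** (energy, contrast, correlation, homogeneity,
  variance, sum average, entropy, dissimilarity) from a symmetric
  co-occurrence matrix over the 13 unique distance-1 offsets of the 3-D
  26-neighborhood, counts summed over offsets before normalization (the
  *merged* aggregation strategy, rather than averaging per-offset
  features).

* **13 GLRLM features** (short/long-run emphases, gray-level and run-length
  nonuniformity, run percentage, the four low/high gray-level emphasis
  combinations, gray-level variance, run-length variance) from maximal
  same-level runs along the same 13 directions, summed. Under merged
  aggregation, run percentage is normalized by $13 \times N_\mathrm{voxels}$
  so it remains in $(0, 1]$.

* **13 GLSZM features**, the zone-size analogues, from 26-connected
  constant-level zones (zones are direction-free, so zone percentage is
  $N_\mathrm{zones}/N_\mathrm{voxels}$).

* **5 NGTDM features** (coarseness, contrast, busyness, complexity,
  strength) following the Amadasun–Kline definitions, with the neighborhood
  mean taken over the in-region 26-neighbors only (edge-corrected) and all
  denominators guarded by $\varepsilon = 10^{-6}$.

Out-of-region voxels never contribute to pairs, runs, zones or
neighborhoods. The counting kernels are implemented in C++ (this is the
pipeline's hot loop — roughly $90 \times 3 \times 26$ regions per cohort)
and are verified, count for count, against an independent pure-R exhaustive
enumeration on every test region of up to 27 voxels.

**Degeneracy policy.** No feature is ever non-finite. Moments of constant
data are substituted by 0, GLCM correlation of a zero-variance matrix by 0,
single-voxel regions get the constant-image limits — and every substitution
carries a flag. Regions smaller than `min_voxels` (default 10) have their
whole feature block flagged; flagged cells are imputed downstream from
training-column medians, never from test rows.

## Assembly and fusion

A subject's row concatenates 57-feature blocks over regions (inner) and
modalities (outer): one modality with 26 regions gives $26 \times 57 =
1482$ features, three give 4446. "Combination" of modalities is feature
concatenation before screening; score-level fusion was considered and not
implemented — concatenation is the simpler mechanism and already dominates
the single sequences in the synthetic experiments. Column names encode the
(modality, region, feature) triple bijectively.

## Feature screening by sparse coding

The screening step sparse-codes the class-indicator vector ($+1$ for
class 1, $-1$ for class 2, one entry per training subject) against the
*transposed* training matrix, so each candidate feature is a dictionary
column over subjects. OMP coefficients are accumulated in absolute value
over 10 stratified 80% subsample repetitions, and the top `k` features by
accumulated magnitude are retained (default `k = 100`). Ties and unfilled
slots fall back to marginal absolute correlation with the indicator, then
column index, keeping selection deterministic under a fixed seed.

One parameter deserves its rationale: the per-repetition pursuit depth is
capped at 15 atoms, well below the classifier's own sparsity cap. Once the
indicator is essentially fit, further pursuit iterations select arbitrary
noise features whose coefficients then pollute the accumulated ranking, so
the cap keeps the union of supports over repetitions commensurate with the
number of features to be selected. The test suite checks that the procedure
recovers planted informative features (against an exhaustive two-feature
least-squares search oracle) and that its overlap with planted features
collapses to chance under permuted labels.

## The sparse-representation classifier

Training feature vectors, restricted to the screened set, form the columns
of the dictionary $F$ (class 1 columns first), each scaled to unit
Euclidean norm. A test vector $f$, prepared identically, is sparse-coded:

$$ \hat\beta = \arg\min_\beta \; \lVert f - F\beta \rVert_2^2
   + \gamma \lVert \beta \rVert_0 , $$

solved greedily by OMP (add the column most correlated with the residual,
re-solve least squares on the active set; stop at `max_atoms = 30` atoms,
at residual norm `tol = 1e-6`, or when no column correlates with the
residual). The constant $\gamma = 0.01$ is carried as metadata: with a
greedy solver the operative sparsity controls are the atom cap and the
tolerance, and no stopping rule is derivable from $\gamma$ alone. Class
residuals use only each class's coefficients,

$$ r_c(f) = \lVert f - F\,\delta_c(\hat\beta) \rVert_2 , \qquad c = 1, 2, $$

and the predicted class minimizes $r_c$; exact ties go deterministically to
class 1. ROC analysis needs a continuous score the residual rule does not
itself define; the package uses the relative residual
$(r_1 - r_2)/(r_1 + r_2 + 10^{-12})$, positive toward class 2, and also
exports the raw residual pair.

**Feature preparation: why min–max and not z-scoring.** Residual
comparability requires a per-feature affine normalization learned on
training rows, and both variants are provided (`fit_normalizer`,
`method = "zscore"` or `"minmax"`). The dictionary uses min–max scaling to
$[0, 1]$ by default, for a geometric reason worth recording. After
symmetric centering, a two-class problem whose separation is dominated by a
mean shift puts the classes on *anti-parallel* rays: class A vectors
$\approx +\delta$, class B vectors $\approx -\delta$. Least-squares
reconstruction is indifferent to sign — a class-B column with a negative
coefficient reconstructs a class-A test vector as well as a class-A column
with a positive one — so the class-restricted residuals lose their
discriminative meaning. Rescaling features to $[0, 1]$ instead keeps all
vectors in the nonnegative orthant — the regime classical SRC was designed
for, where image vectors are nonnegative — and restores residual
discrimination. The test suite demonstrates the contrast directly: on a
planted two-class problem with disjoint activation patterns, the min–max
dictionary cross-validates essentially perfectly while the z-scored one
stays far behind. Screening keeps z-scoring internally (its regression
target is the centered $\pm 1$ indicator, where centering is appropriate).

## Evaluation protocol

Subjects are split into a cross-validation portion and a held-out test
portion at a 2:1 ratio, stratified by class, with the test count per class
`floor(n_class / 3)` and the remainder in the cross-validation portion.
The cross-validation portion is divided into 10 stratified folds (per-class
fold sizes differ by at most one). Within every fold's training partition
the imputer, normalizer, screening and dictionary are re-fit from scratch;
the held-out fold is then classified and predictions are pooled over folds
into a single confusion matrix and ROC. The final model for the held-out
test set (or an external set) is trained on the entire cross-validation
portion. A deliberate-leakage experiment in the test suite (screening on
all rows before cross-validating) measurably inflates accuracy under
shuffled labels, demonstrating that the per-fold refitting is load-bearing
rather than ceremonial.

Reported metrics are accuracy, sensitivity, specificity, PPV and NPV from
the pooled confusion (undefined ratios surface as `NA` with a warning, not
as silent zeros), plus the ROC by threshold sweep with trapezoid AUC —
which equals the Mann–Whitney pair-counting statistic exactly, ties counted
one half; the equality is asserted on random tied instances, and
cross-checked against an independent ROC implementation. When repeated
evaluation is requested, folds are reshuffled under derived seeds, point
metrics are means over repeats, and 2.5/97.5 percentile intervals are
attached; percentile intervals over seeded repeats are this package's
chosen mechanism for interval reporting, since repeat variability under
re-folding is the quantity a reader can actually reproduce.

Positive classes follow the clinical reading of the two tasks: CI (the
merged MCI and AD group) against HC, and AD as the positive class when
separating AD from MCI. Both are configurable.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full study conditions —
90 subjects, three modalities, 26 regions, 4446 features — once for feature
extraction (about a minute), and re-use that matrix across the evaluation
experiments; the permutation null uses 100 fresh label shuffles with a full
10-fold refit each (a few minutes). Unit tests use smaller grids
($\le 32^3$) and parcellations (2–6 regions) chosen so every region still
clears the 50-voxel floor.

Numerical guards, all tested: standard deviations and ranges floored at
$10^{-8}$ in normalizers; NGTDM denominators at $10^{-6}$; OMP stops on
rank-deficient candidate atoms (the support stays exactly sparse, and
coefficients off the support are exact zeros); a zero-norm test vector
yields the all-zero code with both residuals equal, hence the tie
convention (class 1, score 0).

## Known limitations

* The generator's group effect is spatially homogeneous — every region is
  equally informative, which is kinder to feature screening than real
  disease topography would be.
* Min–max preparation is sensitive to single extreme training values; with
  heavy-tailed real features a robust variant (percentile scaling) would be
  the natural extension.
* The screening and interval mechanisms are documented package choices;
  other reasonable designs (frequency-ranked screening, bootstrap
  intervals) exist and would change numbers slightly but not structure.
* Only binary tasks are supported; the three-group problem is handled as
  two clinical contrasts, not as a multi-class classifier.
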