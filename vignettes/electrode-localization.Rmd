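---
title: "Shape-based electrode localization in post-implant CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based electrode localization in post-implant CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and its
assumptions, the parameters that matter, what the synthetic phantom does and
does not emulate, and the design choices made where the design was genuinely
open. It states no empirical number that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The pipeline and its assumptions

A post-implant head CT shows platinum electrodes as the densest objects in
the volume: their radiodensity saturates the scanner's Hounsfield scale,
well above compact bone (~1500-1900 HU). The pipeline is:

    load -> resample to 0.5 mm cubic voxels -> threshold HU > 2500
         -> 6-connected cluster labeling -> six shape features per cluster
         -> Gaussian-kernel SVM -> per-cluster class + centroid

Assumptions worth making explicit:

* **Metal is separable by a single global threshold.** 2500 HU lies between
  bone and metal on standard CT scales. The threshold is strict (`>`); a
  voxel at exactly 2500 is background. Both the value and the strictness are
  configurable (`threshold_metal(vol, hu_threshold)`).
* **Resampling precedes thresholding.** Interpolation of the HU field is
  well-defined; interpolation of a binary mask is not. The workflow order is
  resample → threshold.
* **No gantry tilt.** Tilted DICOM acquisitions are rejected with an error,
  not corrected.
* **No cluster pre-filtering.** Every cluster, including single voxels,
  reaches the classifier; rejection is the classifier's job. This keeps the
  pipeline free of size heuristics that would have to be re-tuned per
  scanner.

## 2. Resampling

`resample_isotropic()` uses an interpolating cubic B-spline (third-order,
no smoothing): a causal/anticausal recursive prefilter (pole $\sqrt3-2$,
mirror boundary, exact initialization for short lines) turns samples into
spline coefficients, then each axis is resampled separably. The output grid
is cell-centered and anchored at the input's first voxel center, with
$n_\text{out} = \lfloor n\,s_\text{in}/s_\text{target}\rfloor$ per axis
(minimum 1), so no sample is extrapolated by more than one voxel and the
affine update is exact. Coordinates outside the input take the nearest-edge
value.

Spline overshoot near metal edges is deliberately **not** clamped: the
downstream threshold sits far above soft tissue, and any clamp range would
be arbitrary. A `clamp_range` argument exists for users who disagree.

Isotropic voxels are what make the shape descriptors rotationally
invariant; on the acquisition grid (e.g. 0.9 x 0.9 x 0.625 mm) a rotated
copy of the same object would have different voxel-space moments.

## 3. The six shape descriptors

For each 6-connected cluster (face adjacency only — two voxels sharing just
an edge or corner are different clusters):

* **volume** — the voxel count $V$ (dimensionless; at 0.5 mm one voxel is
  0.125 mm³).
* **primary/secondary/tertiary axis length** — the axis lengths of the
  *moment-equivalent ellipsoid*: $2\sqrt{5\lambda_i}$ for the eigenvalues
  $\lambda_i$ of the voxel-position covariance (population normalization),
  sorted descending. Before eigendecomposition, $1/12$ is added to each
  diagonal covariance term: this is the second moment of a unit cube about
  its center, so a single voxel gets the axes of its continuous cube
  ($2\sqrt{5/12} \approx 1.291$) and flat or linear clusters keep strictly
  positive axes — no 0/0 in the ratios below.
* **circularity** — primary / secondary. 1 for anything with a circular
  footprint; large for elongated objects (wires, stitches).
* **cylinder similarity** — $((p+s)/4)^2\,\pi\,t\,/\,V$: the volume of the
  cylinder whose diameter is the mean of the two long axes and whose height
  is the short axis, over the cluster's volume.

Closed forms used as test oracles: a solid sphere of radius $r$ has
variance $r^2/5$ per axis, hence axes $2r$ and cylinder similarity exactly
1.5; a cube of side $a$ has axes $1.291a$ (exactly, because the discrete
variance $(a^2-1)/12$ plus the $1/12$ correction is $a^2/12$) and cylinder
similarity $\approx 1.690$; a flat disc has in-plane variance $r^2/4$ and
axial variance $h^2/12$, hence cylinder similarity
$(5/4)\sqrt{5/3} \approx 1.614$ in moment mode.

**Axis-convention decision.** Verbal descriptions of this feature family
sometimes say the ellipsoid "entirely comprises the cluster", but the
standard region-property routine computes the *moment-equivalent* ellipsoid
(a disc's moment axes, $r\sqrt5 \approx 2.24r$, are longer than its
physical diameter but do not bound the cluster). The moment convention is
what such tooling actually computes, so it is the default
(`axis_mode = "moment"`); an `"extent"` mode measuring the cluster's
support along the same principal directions is provided for sensitivity
analysis — under it an ideal flattened cylinder scores cylinder similarity
exactly 1.

Eigenvalue ties (perfect symmetry) are harmless: features depend only on
the sorted values.

## 4. The classifier

A soft-margin SVM with Gaussian kernel
$K(u,v)=\exp(-\gamma\lVert u-v\rVert^2)$, trained by SMO with
maximal-violating-pair working-set selection (no shrinking; deterministic —
no randomness enters training). Multiclass problems (ECoG + depth +
non-electrode) use one-vs-one voting with ties broken by summed decision
values, then class order.

Defaults, all exposed in `gsvm_config()`:

* **box constraint** $C = 1$;
* **standardization** of features to zero mean / unit variance, computed
  from the *training* instances only (per CV fold);
* **kernel scale**: $\gamma = 1/(d \cdot \mathrm{var})$ with $d$ the number
  of features and $\mathrm{var}$ the pooled variance of the standardized
  training matrix (≈ $1/d$ after standardization) — the common
  "scale" heuristic;
* **no class weighting**: with a ~1:5 to 1:10 electrode:distractor
  imbalance, unweighted training reproduces the high-specificity behavior
  this method is known for; a "balanced" mode (per-class $C$ inversely
  proportional to class frequency) is available.

**Cross-validation.** Tenfold, stratified by class (with ~2-3% depth
electrodes, unstratified folds can lose a class entirely), seeded. Fold
membership is derived from *sorted instance keys*, so shuffling the input
rows does not change the split. The headline CV accuracy is the mean of the
ten fold accuracies; the pooled-confusion accuracy is also reported and the
two are asserted to agree within 0.5% on balanced folds. Whether the
original tenfold protocol stratified or standardized is not documented
anywhere we could check; both choices are therefore explicit configuration
with the defaults above.

**Transfer evaluation** trains on one corpus and tests on held-out sets,
reporting per-set confusion matrices plus mean/SD of accuracies. Prediction
never touches test labels (verified by a test that predicts with labels
withheld).

**Feature-subset ablation** evaluates the volume-only subset, volume paired
with each other feature, and the full set, on one shared fold split so
accuracies are comparable. Volume is always included — it is the single
most informative feature, and the ablation question is what it needs to be
paired with.

## 5. The synthetic phantom: what it emulates

`generate_phantom()` builds a deterministic (seeded) scene:

* **Head**: a sphere of soft tissue (40 HU) with a 4 mm skull shell
  (1500 HU) at `head_radius` (default 45 mm) plus 8 mm of scalp, in air
  (-1000 HU). Desk-scale: an adult head is ~80-90 mm; electrode arrays are
  placed by geodesic pitch on the surface, so the local geometry each
  feature sees is the same as on a larger head, at a quarter of the voxel
  count.
* **ECoG electrodes**: discs of 4 mm x 0.5 mm at 10 mm center-to-center
  pitch, in strips (default 8 and 12) and grids (default 6x8), placed on
  the brain-surface sphere with radial normals; arrays are
  rejection-sampled until no two electrode centers come within 80% of the
  pitch.
* **Depth arrays** (optional): solid cylindrical contacts (default
  1.3 mm x 2.0 mm at 5 mm pitch — partial volume turns real sleeve contacts
  into near-solid cylinders anyway) along straight insertion lines; a
  `depth_fused` switch paints a continuous shaft so the contacts fuse.
* **Distractors**: wires (smooth random tubes, 0.8-1.3 mm, starting at the
  scalp and partly leaving the head), stitches (bent 2-5 mm segments,
  0.5-0.9 mm, in and above the scalp), screws (1.5-2.5 mm shafts with a
  2.5-4 mm head, radially in the skull). Placement keeps 4-5.5 mm
  clearances so the PSF cannot bridge distinct objects into one cluster.
* **Acquisition**: in-plane pixel size drawn from 0.44-0.98 mm with
  0.625 mm slices; metal painted at its *pre-blur* radiodensity
  (`metal_hu = 25000`), Gaussian PSF of `psf_sigma = 0.4` mm, HU ceiling
  `clip_hu = 3071`, additive Gaussian noise of 15 HU.

**Why 25000 and not "a bit above bone"?** The observed >2500 HU of implanted
platinum is a *post-PSF* value. A 0.5 mm disc painted at 3100 HU and blurred
with a 0.4 mm PSF peaks at ≈1470 HU — it would never survive the threshold,
and no PSF value can both keep it detectable and reproduce the documented
partial-volume volume inflation (a threshold near the blurred peak shrinks
objects instead). Painting the physically high pre-blur attenuation and
clipping at the 12-bit ceiling reproduces both: blurred cores clamp at
3071 HU while the 2500 HU contour sits outside the physical disc, inflating
cluster volumes to more than double the nominal 50.3 voxels — exactly the
effect the method has to be robust to. Sub-voxel-thin objects additionally
get a guaranteed voxel footprint (a 6-connected chain for tubes, the
mid-plane voxels for discs): an object thinner than a voxel still occupies
part of that voxel in a real CT.

**What the phantom does *not* emulate** — and hence what a green test does
not establish: streak metal artifacts (only isotropic PSF + noise here),
anatomical realism beyond a skull shell, beam hardening, real wire bundles
hugging electrode arrays, and the feature distributions of any particular
scanner. Phantom distractors separate from discs more cleanly than
streak-corrupted real objects; phantom-corpus recognition rates at or near
100% should be read as "the pipeline is correct", not "expect 100% in the
clinic". The paper-reported real-data accuracies (~98-99.7%) are the
realistic expectation, and the acceptance targets are bounds of that order
computed on phantoms.

Ground truth records each object's class and its exact painted-voxel
centroid; `match_detections()` scores detections by greedy one-to-one
nearest-centroid matching within 2 mm (half an electrode diameter) —
unmatched truth electrodes are false negatives, unmatched electrode-class
detections are false positives. `assign_true_classes()` labels clusters for
training by nearest truth centroid within the same tolerance; clusters
matching nothing (e.g. a fused electrode pair, whose merged centroid lies
between the two truth discs) fall to `NON_ELECTRODE`.

## 6. Numerical choices and degenerate inputs

* Resampling a volume to its own spacing is the identity to <1e-6 HU
  (exact prefilter initialization matters for short axes).
* Cluster labels are assigned in scan order of each component's first
  voxel: deterministic across runs and platforms.
* The "at least six faces attached" phrasing sometimes used for
  6-connectivity is read as standard face adjacency, *not* a ≥6-neighbor
  degree filter — a degree filter would erase every surface voxel of every
  object.
* Empty masks, empty feature tables and empty prediction inputs are valid
  and produce empty outputs; a metal-free CT yields an empty detections
  file with a warning, exit status 0.
* SMO convergence tolerance 1e-3 with an iteration cap of 200·max(n, 1000);
  hitting the cap raises a warning. Training is validated against an
  independent SVM implementation in the test suite.
* Standardization guards zero-variance features (divisor 1).
* Wires and stitches located outside the head are kept as non-electrode
  instances — nothing is cropped to the skull.

## 7. Known limitations

* **Fused electrodes remain unsolved** (as in the underlying method):
  overlapping discs produce one merged cluster, counted as a single
  detection; the phantom can generate such pairs
  (`overlap_electrode_pairs`) and the tests assert the fusion, not a split.
* Depth-electrode support is secondary and untested against any real
  SEEG data; the phantom's solid-cylinder contacts are an idealization.
* The DICOM reader handles uncompressed explicit/implicit-VR little-endian
  single series only.
* In the feature-subset ablation on phantom corpora, the weakest
  volume-containing pairs (volume+tertiary axis, volume+cylinder
  similarity) hover around the 99% CV-accuracy mark and can dip a few
  tenths below it depending on the corpus seed; the full feature set is
  consistently above. The acceptance report computes the exact values.
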