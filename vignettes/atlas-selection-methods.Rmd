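---
title: "Volume-feature atlas selection for multi-atlas pelvic segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-feature atlas selection for multi-atlas pelvic segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multi-atlas segmentation (MAS) labels a new CT volume by deformably
registering a handful of previously contoured images (atlases) onto it,
propagating their contours through the resulting deformation vector fields,
and fusing the propagated label maps by majority voting. The step that most
strongly determines output quality is *which* atlases get registered:
deformable registration degrades when the target and atlas differ by a large
organ-volume change (a full versus empty bladder can differ six-fold), and a
badly matched atlas contributes a wrong contour to the vote.

`masel` implements four selection strategies around a common registration
and fusion core, for female pelvic CT structures (bladder, rectum, left and
right femoral heads, bone marrow, body external):

* **cMAS** — the conventional approach: deformably register *every* atlas to
  the target, rank by the normalized cross-correlation (NCC) between the
  target and the warped atlas image, fuse the top `n`.
* **SAGA** — subgroup the atlas library by k-means on per-structure volume
  features, assign the target to its nearest subgroup, then rank the
  subgroup members exactly as cMAS does. Volume features gate the candidate
  pool; image similarity ranks within it.
* **FASA** — rank all atlases by the Euclidean distance
  `D = ||V_atlas − V_target||` between min–max-normalized volume feature
  vectors; register only the `n` closest. No similarity evaluation at all.
* **SIM** — rank by Mattes-style mutual information after rigid
  registration; register only the top `n`. This is the intensity-only
  control for FASA.
* **random** — seeded uniform choice; the floor any informed strategy must
  beat.

The shortlist size defaults to `n = 5` and the number of subgroups to
`k = 4`, the operating point balancing quality against registration cost.
The selection-cost structure follows from the definitions: cMAS performs one
deformable registration per atlas per target, SAGA one per subgroup member,
FASA/SIM/random exactly `n`.

## Volume features and normalization

Features are per-structure volumes in cc computed by voxel counting
(`volume_of_label`), ordered as (body, bladder, rectum, left femoral head,
right femoral head, bone marrow); the body-external contour is included by
default and configurable away. Volumes are normalized per structure to
[0, 1] by min–max over the *atlas set only*; min–max is the unique affine
map achieving those bounds on the fitting set. The identical affine map is
then applied to the target's volumes, deliberately without clamping, so a
target outside the atlas range stays ordered correctly in feature distance.
Target volumes are taken as given input — in the synthetic experiments they
are the exact volumes of the deformed ground-truth labels; estimating them
on clinical data is an open problem outside this package's scope.

## Subgrouping

`fit_subgroups` is Lloyd's k-means on the normalized feature matrix,
minimizing the within-cluster sum of squared Euclidean distances. Details
that the pipeline's determinism contract pins down:

* initial centroids are `k` distinct data points chosen by seeded sampling
  over atlases in lexicographic id order, so a permutation of the input
  yields the same partition;
* the best of `restarts = 10` seeded initializations by final objective is
  kept; on 8-point/k = 2 instances this attains the exhaustive optimum over
  all 2^8 assignments (a tested property);
* an empty cluster arising during iteration is re-seeded from the point
  farthest from its assigned centroid, keeping `k` fixed;
* nearest-centroid assignment breaks ties toward the lowest cluster index.

At desk scale the default `k = 4` can leave a subgroup smaller than the
shortlist; the experiment runner then reduces `k` stepwise (never below 2)
until every subgroup holds at least `n_atlases` members, honouring the
constraint that the fused shortlist must fit inside any assigned subgroup.

## Registration stand-in

The clinical study behind this problem used a commercial hybrid
(anatomically constrained) deformable registration engine. `masel` replaces
it with an open, same-modality stand-in whose contract is stated and tested
rather than matched to the commercial internals:

* **Rigid**: Nelder–Mead over three Euler angles and three translations
  maximizing joint-histogram MI, multi-resolution (block-mean pyramid),
  translation initialized from the intensity centre-of-mass offset. Two
  numerical details matter. The metric is evaluated on a half-voxel-offset
  sample grid, because grid-aligned poses otherwise carve a spurious local
  maximum into the MI surface exactly at the identity. And the optimizer's
  histogram uses bilinear (partial-volume) bin spreading, which smooths the
  cost the way Parzen windowing does; the exported `mattes_mi` keeps hard
  equal-width binning so that `MI(a, a)` equals the marginal entropy at the
  same binning, a tested identity. A coarse ±10° sweep per rotation axis at
  the coarsest level seeds the simplex inside the correct basin on
  near-symmetric anatomy.
* **Deformable**: free-form deformation — per-voxel displacement is the
  first-order B-spline (trilinear) interpolation of a control grid —
  minimizing intensity-range-normalized mean squared difference plus a
  second-difference bending penalty (`lambda`, default 1e-4), optimized by
  L-BFGS-B with the exact analytic gradient (adjoint splatting of the
  residual-weighted image gradient onto the control grid). The pyramid
  refines both the image (factors 4, 2, 1) and the control spacing
  (64 → 32 → 16 mm), which is what lets an 8 mm warp escape local minima at
  the coarse level and be sharpened at the fine ones. The returned field is
  the total displacement (rigid initialization included) on the fixed grid;
  if optimization fails to improve the residual, the initialization is
  returned unchanged, so the residual never worsens.

MSD is a valid data term here because all images are same-modality CT-like.
The commercial engine's anatomical-constraint term is deliberately not
reproduced; any registration-dependent validation is therefore
property-based (ground-truth recovery on phantoms), never value-matching
against the clinical tables.

On a noise-free textured phantom the deformable stand-in recovers a known
smooth 8 mm sinusoidal warp with mean endpoint error below 2 mm over the
organ voxels. Two conventions in that statement are deliberate. The
validation phantom carries a smooth deterministic intensity texture
(`texture_amp`), because on a piecewise-constant phantom only the
boundary-normal field component is observable — no intensity-driven method
can recover the tangential component along a homogeneous region's surface.
And the error is averaged over organ voxels, the regions whose anatomy
constrains the field and whose displacement the pipeline actually consumes;
in surrounding air the field is unconstrained and its "error" against the
analytic warp is meaningless.

## Evaluation

* **DSC** = `2|A ∩ B| / (|A| + |B|)`, integer arithmetic before the final
  division; fused multi-label maps are split into binary masks per
  structure.
* **95HD**: surface voxels are structure voxels with at least one 6-connected
  neighbour outside the structure (the image boundary counts as outside),
  taken as voxel centres in physical mm. Directed nearest-surface distances
  are computed both ways with an exact anisotropic squared Euclidean
  distance transform, *pooled*, and the 95th percentile (linear
  interpolation between closest order statistics, `quantile` type 7) is
  reported in cm. The pooled symmetric convention — rather than the maximum
  of two directed percentiles — is one of two defensible readings; it is
  pinned by an all-pairs brute-force oracle test. Pooling also makes the
  metric symmetric under swapping the two masks.
* **Paired comparisons**: two-tailed paired t-tests at a single 0.05
  threshold, one per (strategy, structure, metric) against a reference
  strategy, with no multiple-testing correction — a deliberate mirror of
  how such comparisons are conventionally reported for this problem, and a
  known limitation.

## The synthetic cohort

No clinical data ships with the package; every claim is exercised on a
deterministic phantom cohort (`generate_cohort`). Each subject is a CT-like
volume (default 96 × 96 × 64 at 2 mm isotropic — small enough for
desk-scale registration, large enough for distinct structures) holding a
soft-tissue body ellipsoid, a bladder ellipsoid, a curved rectal tube, two
spherical femoral heads and two bone-marrow columns, with CT-plausible
constant intensities (≈ 40/10/30/700/200 HU, air −1000) plus Gaussian noise
(sd 8). Intensities are plausible constants, not calibrated HU: MI, NCC and
MSD only need consistent contrast. Each structure is carved as the level
set of a continuous field holding exactly `round(volume / voxel volume)`
voxels, so realized volumes match requests to within half a voxel at any
resolution.

Cohort-level variation encodes the physiology that makes atlas selection a
real problem:

* bladder and rectal volumes are drawn independently and uniformly over the
  clinical cohort ranges (70.89–437.09 cc and 21.3–115.04 cc) — organ
  filling is independent of patient size;
* body, femoral-head and bone-marrow volumes follow a shared habitus
  latent, so global appearance co-varies across structures but is largely
  uninformative about bladder filling;
* each subject is warped by the sum of three smooth Gaussian radial-basis
  fields: an organ-linked shared warp whose signed coefficient follows the
  subject's bladder/rectum deviation from the cohort midpoint (6 mm max), a
  habitus-linked shared warp (3 mm), and a subject-specific random warp
  (1.5 mm). Bump widths (σ = 35–45 mm) are well above the amplitudes, so
  displacement gradients stay below 1 and the maps remain diffeomorphic.

The organ-linked component guarantees, by construction, that inter-subject
deformation magnitude correlates with organ-volume mismatch (tested at
r > 0.5 over pairwise bladder-volume differences) — the structural premise
under which volume-aware selection can outperform intensity-only selection.
The habitus component keeps global similarity partly orthogonal to organ
volume, which is why SIM and FASA genuinely disagree. What the phantoms do
*not* emulate: anatomically realistic shape detail, soft-tissue texture,
contrast agents, metal artifacts, scanner-dependent noise spectra. Passing
tests on this cohort validate the pipeline's mechanics and the direction of
the selection-strategy comparison under the stated premise; they are not
evidence about clinical effect sizes.

## The desk-scale experiment

The shipped end-to-end validation (also what `scripts/acceptance.R` runs)
uses 26 subjects: a 20-atlas library and 6 held-out targets, one fold.
Each target is derived from its held-out subject by an extra known 5 mm
warp; its ground-truth labels and exact volumes come with it. The
experiment uses a faster registration profile than the package defaults
(two pyramid levels instead of three, rigid levels 4/2) — rankings and
label propagation at 2 mm voxels do not need the final sub-millimetre
polish, and this keeps the full five-strategy run around ten minutes on one
CPU. Checked claims: mean bladder DSC orders SAGA > SIM and FASA > random,
and registrations demanded per target order cMAS (20) ≥ SAGA (subgroup
size) ≥ FASA = SIM = 5. With six targets these are directional claims under
fixed seeds, not effect-size reproductions — the clinical tables depend on
a private 100-patient cohort and a commercial registration engine and are
out of reach by design.

Normalizer and subgroups are fit on the atlas split only; a test asserts
bitwise invariance of their parameters to arbitrary changes in the held-out
subjects. Registrations are cached per (target, atlas) within a run, so
strategies sharing candidates (SAGA inside cMAS's register-all) reuse work.

## Degenerate inputs and tie rules

Ties in feature distance or similarity rank break lexicographically by
atlas id; nearest-centroid ties toward the lowest cluster index;
majority-vote ties between distinct top labels go to background. A constant
image yields MI 0 with a warning (zero marginal entropy). DSC of two empty
masks and 95HD of any empty mask are errors, not numbers. A structure
volume smaller than one voxel, a structure that cannot be placed inside the
body envelope, and bladder/rectum requests outside the cohort ranges are
generation errors.

## Known limitations

* The deformable stand-in is intensity-only; no anatomical constraint term,
  no STAPLE or locally weighted fusion (majority voting only).
* k-means is the normative subgrouping method; soft assignments and model
  selection for `k` are out of scope.
* The t-tests are reported at a single threshold without correction.
* Phantom realism is limited to what the selection problem structurally
  needs; absolute DSC/95HD values on phantoms do not transfer to clinical
  data.
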