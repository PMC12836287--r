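---
title: "Atlas-based dose mimicking and complete-block generation: methods"
author: "dosemimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based dose mimicking and complete-block generation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Helical tomotherapy treats left-sided breast cancer with excellent target
conformity, but its rotational delivery paints a diffuse "low-dose bath"
(roughly 1–5 Gy) across the contralateral lung and breast. Tangential
partial-arc VMAT (t-VMAT) plans have the opposite profile: slightly worse
conformity, but very little contralateral spillage. A *complete block* — an
avoidance structure through which no beamlet may pass at any point along its
path — can force a helical plan to respect t-VMAT-like low-dose anatomy, but
only if the block is patient-specific: a generic block either blocks too
little (no sparing) or too much (the optimizer routes fluence through worse
paths and treatment time explodes).

`dosemimic` implements the knowledge-based workflow that produces such
blocks: predict, for a new patient, the 3D dose a tangential plan *would*
deliver, take the predicted 2-Gy isodose volume as the territory the beam is
allowed to use, and define the complete block as everything else inside the
body.

## The prediction model

The predictor is atlas-based deformable-image-registration (DIR) dose
mimicking, not a learned model:

1. **Atlas construction.** Every atlas CT is registered (affine, then
   B-spline) to one designated reference patient, and its planned dose is
   pulled back into the reference frame with the resulting displacement
   field.
2. **Test registration.** A new patient's CT is registered to the same
   reference, giving a field $F$ (fixed frame: the reference) and its
   inverse $F^{-1}$ (computed by fixed-point iteration
   $v_{k+1}(x) = -u(x + v_k(x))$).
3. **Similarity weighting.** In the reference frame, the warped test CT is
   compared with each member's warped CT by a slice-wise structural
   similarity index (SSIM): mean local SSIM per axial slice (Gaussian
   window, $c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$), averaged over slices
   intersecting the body. Similarities $s_i$ become convex weights
   $w_i = s_i^p / \sum_j s_j^p$.
4. **Fusion.** Every member dose is pulled into the test geometry through
   $F^{-1}$ and the prediction is $\hat D = \sum_i w_i D_i$. The result is
   voxel-wise a convex combination, so $\hat D$ inherits nonnegativity and
   the member dose range.

The predicted dose is deliberately *not* trusted near steep gradients — DIR
fusion blurs dose edges. The workflow only consumes the predicted **2-Gy
isodose surface**, which lives in the flat low-dose tail where this
limitation is least pronounced.

### Design choices in the weighting

The similarity is computed in the *reference* frame (warped test CT vs.
member warped CTs) because that is the only geometry in which all stored
atlas volumes are directly comparable. The SSIM dynamic range is fixed to a
2000 HU CT window (−1000 to +1000) rather than estimated per pair, so that
air-dominated slices cannot inflate similarity; slices not intersecting the
body are excluded for the same reason. Negative or zero similarities are
clamped to $\varepsilon = 10^{-6}$ before normalization (weights must stay
nonnegative). The sharpening exponent defaults to $p = 1$ (plain
normalization); as $p \to \infty$ the prediction converges to the single
most similar member, which is exposed for sensitivity analyses.
Whether the reference's own dose participates is a genuine ambiguity in
atlas workflows; we include it (an atlas of $n$ cases contributes $n$
doses).

## Registration

The registration engine is intensity-based with a mean-squared-error (MSE)
metric (appropriate for same-modality CT):

* **Affine stage** — translation, rotation, scaling and shear, parameterized
  as $p(x) = A(x - c) + c + t$ about the volume center $c$. Multiresolution
  (3 levels, downsampling 4×4×2 at the coarsest), 20 gradient iterations per
  level with analytic gradients, diagonal preconditioning (the linear part's
  curvature scales with the squared lever arm), adaptive step with
  backtracking, and a small seeded random initial translation.
* **B-spline stage** — cubic free-form deformation on a uniform 50 mm
  control grid, seeded by the affine stage (the moving image is resampled
  through the affine once per level). Same 3 levels, 30 iterations per
  level; analytic gradient of the MSE with respect to the control
  coefficients; steps start sub-voxel (0.5 mm) and grow only while the
  metric improves, which keeps flat-region coefficients from chasing edge
  noise. Out-of-support voxels are excluded from the metric — without this,
  border fill values masquerade as huge intensity errors and corrupt the
  field.
* Both images at every level receive the same Gaussian pyramid prefilter
  (σ = half the downsampling factor, in voxels) so neither side carries
  systematically more interpolation blur than the other.

The exported result is a single displacement field on the fixed grid in
pull-back convention, $\text{warped}(x) = \text{moving}(x + u(x))$, with
$u(x) = A(x + u_b(x) - c) + c + t - x$. "30 iterations" is interpreted per
resolution level (the alternative — total — is configurable by lowering the
per-level count). The similarity metric is not dictated by the workflow
definition; MSE is the declared default, not an inferred intent.

Measured contracts on the synthetic cohort (asserted in the test suite):
self-registration stays within 0.5 mm mean displacement over the body; a
6 mm rigid translation is recovered to well under 2 mm; inversion of cohort
deformation fields leaves a mean residual under 0.5 mm.

## The synthetic cohort

No imaging data ship with the package; the `phantom_synth` module generates
a seeded, fully reproducible stand-in cohort. The template is a thorax-like
phantom on a 96×96×48 grid at 3×3×5 mm (the dose-grid resolution and CT
slice thickness of the clinical setting it emulates): an elliptic-cylinder
chest with protruding breast mounds, two ellipsoidal lungs (−700 HU), a
left-shifted spherical heart, a left breast + chest-wall target
(`PTV_Breast`, ≈716 cc, inside the 300–900 cc clinical range), a superior
supraclavicular target (`PTV_SCF`, ≈86 cc), contralateral breast, esophagus
and spinal cord (a +300 HU cylinder that anchors the registration
posteriorly). CT values get a 0.6-voxel Gaussian blur emulating
partial-volume edges; perfectly sharp binary edges are both unrealistic and
needlessly hostile to interpolation.

Cohort members are smooth random warps of the template: cubic B-spline
coefficients on a 50 mm control grid drawn $\mathcal N(0, (2a)^2)$ for
amplitude $a$ (default 5 mm), evaluated on the image grid and clamped to
$|u| \le 2a$. The clamp guarantees invertibility in practice (displacements
stay below the control spacing). CT warps linearly, masks by nearest
neighbour, and each member's dose is synthesized *in its own deformed
anatomy* — so the "ground truth" dose is consistent with the member's
geometry, not a warped copy.

Two analytic dose styles encode the clinical contrast the workflow exists
for:

* **tangential** — full prescription inside the targets and along two
  oblique corridor slabs through the breast (±8° about the chest-wall
  tangent, 30 mm half-width), falling off as $\exp(-d/12\,\text{mm})$
  outside the slabs and beyond the target's cranio-caudal extent; the deep
  chest core sees no primary fluence and the corridors stop at a medial
  field border, so contralateral structures receive almost nothing
  (contralateral lung mean ≈ 0.8 Gy on the template).
* **helical** — prescription-conformal target dose plus a low-dose bath
  $6\,\text{Gy} \cdot \exp(-d(x,\text{PTV})/40\,\text{mm})$ everywhere in
  the body (contralateral lung mean ≈ 2.1 Gy).

Both styles are clipped to 1.1 × prescription and vanish outside the body.
The helical 2-Gy isodose volume exceeds the tangential one on every
generated case — that inequality is the premise of the whole workflow, and
it is asserted as a property test. What the generator does *not* emulate:
beam transport (no divergence, attenuation or scatter physics), breathing
motion, CT noise and artifacts, and realistic dose gradients near the
target; conclusions from passing tests are about the workflow's mechanics,
not about clinical dosimetry.

## Block generation and evaluation

The complete block is `body AND NOT isodose(2 Gy)` on the predicted dose,
then morphological closing (5 mm) and opening (2 mm) with true spherical
elements (implemented through an anisotropic 3D Euclidean distance
transform) for geometric continuity, and finally — because a *complete*
block must never intersect beam-usable territory — the isodose volume is
subtracted again after smoothing. The threshold is inclusive
($\ge 2$ Gy), matching the $V_x$ convention; the planning-constraint checks
(block $D_{max} < 2$ Gy, $V_1 < 50\%$) are strict, matching how such
constraints are written. The smoothing radii are declared defaults, not
reverse-engineered values: the clinical smoothing step was performed in a
TPS whose method is unspecified.

Plan quality uses exact voxel-counting metrics: cumulative DVHs (0.01 Gy
bins), $V_x$ / $V_{x\%}$ / $D_{x\%}$ (the latter interpolated between
sorted voxel doses), mean/max/min, integral dose (mean dose × volume in
liters at unit density, Gy·L), Dice overlap, the Paddick conformity index
at the 95% isodose, and the ICRU-83 homogeneity index
$(D_{2\%} - D_{98\%})/D_{50\%}$. The conformity/homogeneity definitions are
an open choice — the clinical values this workflow was validated against do
not name theirs — so both indices are switchable (`method = "coverage"`,
alternate HI formulations can be derived from `d_at_volume`) and every
report states which definition produced it. No attempt is made to match any
particular clinical CI/HI values.

## Validation and statistics

Leave-one-out cross-validation rebuilds the atlas without the held-out case
(reference: the first remaining case in id order, deterministically, unless
pinned), predicts the held-out dose, and scores the Dice coefficient of the
predicted vs. actual 2-Gy isodose. Pairwise registrations are memoized
across folds — in a LOO sweep the same (moving, fixed) pairs recur, and
recomputing them would only add runtime, not information. On the default
10-case helical cohort the mean DSC is ≈ 0.95 (the test suite asserts
≥ 0.80); a degenerate cohort of identical phantoms is recovered with DSC
≥ 0.99 and mean absolute dose error ≤ 0.5 Gy.

The statistical harness mirrors a small-cohort comparison design:
Fisher's exact test for categorical baseline variables (two-sided by the
point-probability convention — the one that reproduces the published
contingency p-values 0.634 / 0.601 / 1.000; a doubling convention would
not), Mann–Whitney U for independent continuous comparisons (exact for
small tie-free samples), Friedman omnibus over paired plan arms followed by
Wilcoxon signed-rank post hocs, and a step-down Holm–Bonferroni correction
implemented in the package (not delegated) and verified against a
sequential-rule enumeration oracle. Standard test statistics themselves are
delegated to `stats::` — re-implementing `wilcox.test` would add risk, not
value — but every convention-sensitive quantity is pinned by an oracle
test.

## Numerical choices and degenerate inputs

* Grids are axis-aligned DICOM-LPS; voxel (1,1,1)'s center sits at the
  geometry origin; masks are sampled at voxel centers; contours rasterize
  by the even-odd rule per axial slice.
* Resampling: linear for scalar volumes, nearest for masks; out-of-support
  voxels become 0/`FALSE`; a zero-spacing target is an error.
* Dose grids are resampled onto the CT geometry at load; all downstream
  math lives on one grid per patient. RTDOSE rasterization before the block
  subtraction likewise happens on the CT grid.
* SSIM of two volumes with zero declared dynamic range is 1 if they are
  identical, else 0. All-nonpositive similarity vectors fall back to
  uniform weights with a warning.
* Field inversion stops at a 0.1 mm mean residual or 20 iterations; points
  that map outside the field support keep their current estimate and are
  excluded from the residual. Non-convergence warns and returns the result
  (with the residual attached) rather than failing the pipeline.
* Empty masks: DVH and dose statistics refuse them; integral dose returns 0
  with a warning; an empty block is reported "not applicable" rather than
  passing or failing constraints; an empty structure exports as a valid
  zero-contour ROI.
* Two empty masks have Dice 1 (they agree everywhere).

## Problem sizes

The shipped defaults are desk-scale by design: a 10-case cohort on the
96×96×48 grid for the leave-one-out study (a full sweep is a few minutes on
one core thanks to registration memoization), 4 identical phantoms for the
degenerate recovery check, and ≤ 20³ random grids for the metric-oracle
suites. Larger cohorts and grids only change runtime, not any code path.

## Known limitations

* The registration optimizer is first-order gradient descent; it has no
  diffeomorphic guarantee, and very large deformations (beyond the
  generator's clamp) can fold.
* The DICOM codec covers the explicit-VR little-endian subset the workflow
  exchanges (CT series, RTDOSE, RTSTRUCT with closed planar contours,
  axis-aligned geometry); it is not a general DICOM implementation, and
  RTPLAN / TPS databases are out of scope.
* Predicted dose values are only trustworthy as a *low-dose envelope*;
  nothing downstream should read high-dose-region values off the
  prediction.
* The synthetic cohort shares one template topology; the workflow's
  robustness to, e.g., mastectomy-vs-lumpectomy anatomy differences is not
  exercised here.
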