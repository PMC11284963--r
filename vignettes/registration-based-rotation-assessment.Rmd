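---
title: "Surface-registration assessment of 3D femoral rotation change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-registration assessment of 3D femoral rotation change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Derotational interventions on a growing femur — corrective osteotomy or
guided growth — change the twist of the distal femur relative to the
proximal femur about the bone's long axis, and often have smaller,
unintended effects in the other anatomical planes. Quantifying that change
(ΔFR, the femoral rotation difference between a baseline scan W0 and a
follow-up scan W12) from two CT-derived surface models is harder than it
sounds: between the scans the bone has grown (its volume may more than
double over twelve weeks), its shape has drifted, natural torsional change
has accrued, and the two segmentations share no vertex correspondence.
Classical 2D axial measurements and landmark-based 3D torsion measures are
sensitive to slice and landmark choice; a surface-registration approach
instead uses the entire bone surface as a dense landmark set.

`deltafr` implements that approach end to end:

1. **Initial alignment.** The baseline model is registered onto the
   follow-up model with a *similarity* transform (uniform scale, rotation,
   translation) — principal-axis prealignment followed by iterative closest
   point (ICP). Scale compensates growth; the aligned model W0^T^ preserves
   the baseline's shape.
2. **Sectioning.** W0^T^ is cut by its own bone frame into a proximal
   section (40% of the bone length: head, neck, both trochanters and part
   of the shaft) and a distal section (15% from the distal end: the
   condyles).
3. **Section registration.** Each section is registered to the *full*
   follow-up mesh, by default with a uniform scale clamped to [0.9, 1.1]
   (see *Numerical choices*).
4. **Decomposition.** ΔFR is the relative rotation of the distal over the
   proximal registration, `R_D R_P^-1`, expressed in the bone frame and
   reported both as extrinsic XYZ Euler angles and as a rotation vector.
   `(0, 0, 0)` degrees means no rotational change.

Because ΔFR is a *relative* rotation, it is invariant to how the initial
alignment distributed any residual error: repositioning both scans by a
common rigid transform, or composing the baseline with an arbitrary
similarity, leaves the components unchanged (both properties are tested).

## The reference frame of the components

Euler components are only meaningful in a stated frame. The package
expresses ΔFR in the source bone frame *transported by the proximal
registration* (`B = R_P B_{W0^T}`): conceptually, the anatomical axes of
the un-twisted anatomy placed in follow-up space. In a same-bone
twist-recovery experiment this frame coincides exactly with the frame in
which the twist was applied, so the decomposition returns the nominal
angles; in a cross-scan assessment it is the natural anatomical frame of
the registered baseline.

The frame itself (`principal_frame()`) takes its long axis from the
dominant eigenvector of the vertex covariance. The transverse axis is
deliberately *not* taken from the remaining eigenvectors: an elongated bone
is nearly tubular, its transverse eigenvalues are close, and the
corresponding eigenvectors can swing by tens of degrees between two scans
of the same animal — which would mix the x and y components of ΔFR.
Instead the transverse axis is anchored on anatomy: the mean transverse
direction of the most radially distant vertices in the proximal quarter of
the bone (the head/neck/trochanter apex), a landmark that is stable to
well under a degree across growth. For transversely symmetric shapes
(boxes, cylinders) the second eigenvector, signed by the skewness of its
projections, is the fallback. The proximal end, when no hint is given, is
the bone half whose vertices lie further on average from the long axis —
the offset femoral head and trochanters outweigh the condyles.

## Registration: design and numerical choices

**Correspondences.** ICP runs point-to-surface by default: each sampled
source vertex is projected onto the closest point of the target
triangulation (nearest vertex by kd-tree, then the exact closest point
among its incident triangles). Nearest-*vertex* matching is available as an
option, but on a ~4000-vertex femur the azimuthal vertex pitch of the shaft
is about 10°, and vertex matching locks the optimisation onto the mesh
lattice well before the sub-degree accuracy the measure needs. After the
surface fit, a short nearest-vertex pass is attempted: when the two meshes
share vertex layout (same-bone experiments) it snaps the fit to machine
precision; when they do not, it fails to lower the surface RMS and is
discarded.

**The fit.** The inner step is the closed-form least-squares similarity
(SVD of the cross-covariance with the sign-corrected smallest singular
direction, so reflections are never returned). Scale estimation can be
clamped; the rigid fit is the special case of unit scale.

**Stopping.** Tangential sliding on smooth surfaces makes the RMS a poor
convergence signal on its own, so iteration stops when the per-iteration
*transform update* drops below 2×10^-4^ degrees of rotation and 2×10^-5^ mm
of translation (or on relative RMS change below 10^-7^, or at
`max_iterations`, default 200). With no trimming the recorded RMS sequence
is non-increasing, the classical ICP guarantee.

**Global search.** Point-to-point ICP is local, and a femur offers two
traps: the near-degenerate transverse principal axes (azimuth cannot be
read off the eigenvectors) and condylar aliasing (azimuthal shifts that
swap the two condyles produce convincing false minima). The package
therefore treats every registration as a small multi-start problem:

* `prealign()` matches long axes in both orientations and scans the full
  azimuth circle plus a small tilt grid, ranking candidates by *trimmed*
  nearest-neighbour RMS — trimming matters because a locally derotated
  region is a block of outliers whose squared distances would otherwise
  outvote an exact fit of the remaining anatomy.
* The whole-bone alignment refines one candidate per azimuth sector with a
  cheap trimmed ICP and keeps the best, then polishes scale, rotation and
  translation on the best half of the correspondences (a consensus refit;
  fixed-fraction trimming alone still lets a deformed block drag the scale
  by a few tenths of a percent).
* Each section registration builds candidate starts spanning the
  physiologic search space: the right-handed principal-axis assignments of
  the section onto a congruent end chunk of the target (cut to the
  section's physical height, including the transverse-swap assignments
  that cover eigenvalue-order changes), plus a grid of bone-frame tilts
  (±24°) and azimuths (±40°) with centroid-matched translation — the
  centroid matching also absorbs differential axial growth. A batched
  nearest-neighbour scan ranks the candidates, short ICP scouts probe the
  best few distinct basins, and the lowest final RMS wins.

**Section scale.** Sections fit a uniform scale clamped to [0.9, 1.1] by
default. The initial alignment resolves the growth scale only to a few
tenths of a percent when part of the anatomy changed between scans, and a
rigid fit of a slightly mis-scaled copy biases the recovered rotation by
up to a degree; the clamped similarity absorbs the residual without
allowing the shrink-collapse failure mode of open correspondences.
`section_scale = FALSE` restores rigid section fits.

**Conditioning.** A near-axisymmetric section (transverse covariance
eigenvalues within 5%) makes long-axis rotation ill-conditioned; the
assessment warns when it detects one.

## The virtual twist (ground truth)

`apply_virtual_twist()` rotates each vertex about a fixed pivot on the long
axis by `Rz(w a_z) Ry(w a_y) Rx(w a_x)` in bone-frame axes, where the
weight `w` follows a C^1^ cosine ramp of the vertex's *pre-twist* axial
fraction: zero proximal to 40% of the bone length from the distal end,
saturating to one at 20%. The choices that matter:

* Because the ramp saturates at 20% — proximal to the 15% distal assessment
  section — the distal section undergoes *one exact rigid rotation* by the
  nominal angles, which is what makes the nominal angles a well-defined
  ground truth (verified to 10^-9^ degrees in the tests).
* The single fixed pivot (the long-axis point at the ramp start) keeps the
  fully rotated zone a rigid body; per-slice pivots would couple
  translation into the twist.
* The X-then-Y-then-Z application order about fixed bone axes is the source
  of the small cross-axis interference seen with simultaneous tri-axial
  twists.
* A linear ramp profile is available for comparison; vertices proximal to
  the ramp start are returned bitwise unchanged.

## The synthetic cohort

No imaging data accompanies the method, so the package generates its own
study population. `generate_femur()` builds a stylized immature femur as a
closed parametric tube: vertex rings along a bowed long axis with a
direction- and height-dependent radius — metaphyseal flares, a mildly
elliptic shaft, an offset head/neck controlled by neck length, neck-shaft
angle and anteversion, a greater-trochanter bump, and two condylar lobes —
capped by two pole fans. The construction is watertight by design (Euler
characteristic 2, every edge shared by two faces), deterministic per seed,
resolution-controlled (default 4000 vertices), and has no rotational
symmetry about the long axis, which is exactly what makes ΔFR observable.
Surface noise is independent Gaussian displacement along vertex normals
(default 0.1 mm, sub-voxel for 0.8 mm CT slices).

`grow_femur()` rebuilds the bone at follow-up: every linear parameter
scaled by 1.35 (volume ratio ≈ 2.7, matching a doubling of body weight),
an extra 8% axial elongation, per-parameter radius jitter (3% sd), a
natural torsion drawn from N(3°, 2°) applied through the same twist
machinery, fresh surface noise, and — by default — an independent re-mesh
(different resolution and grid phase) so the two scans share no vertex
correspondence, as two independent segmentations would not.
`generate_cohort()` adds ±10% per-subject jitter on radii and lengths with
seeds derived from one master seed. Neck and anteversion *angles* are not
jittered across subjects: angle jitter would change each subject's true
anatomical frame and conflate frame recovery with detection error in the
harness metrics.

What the generator does **not** emulate: real cortical/trabecular surface
texture, segmentation artefacts at joints, metal artefacts, partial-volume
effects, growth-plate-localized remodelling, or anatomically validated pig
morphometry. Passing the verification and validation contracts on this
cohort demonstrates the *method's* geometric correctness and its
robustness to growth-like non-rigid change, re-meshing and noise — not its
accuracy on any particular scanner or species.

## Verification, validation and metrics

`run_verification()` mirrors the same-bone protocol: each follow-up femur
is virtually twisted by (a, a, a) degrees for a in {5, 10, 15, 20} and the
rotation change between the untwisted and twisted mesh is assessed — n × 4
experiments. `run_validation()` mirrors the cross-scan protocol: for every
ordered (W0 of subject i, W12 of subject j) pair the untwisted baseline
ΔFR is measured once (shared across angles), then each twisted assessment
is corrected for it — n² × 4 experiments, 484 at n = 11. Simultaneous
tri-axial twists match that count (no extra axis factor); per-axis single
twists are available via `axes = "single"`.

Growth correction composes rotations by default
(`R_twisted R_baseline^-1`); literal component-wise subtraction is provided
(`mode = "subtract"`) and reported alongside in the records, the two
agreeing exactly for commuting same-axis rotations.

Metrics follow the standard agreement toolkit, with sample (n−1) standard
deviations throughout: normalized detection (100 × detected/true per axis,
undefined where the true angle is zero), detection error (|mean normalized
− 100|), mean absolute error of the normalized angles, the coefficient of
variance (100 × sd/mean), and Bland–Altman limits of agreement (mean
difference ± 1.96 sd), relative differences for verification and absolute
for validation.

## Problem sizes and tolerances used in the checks

The test suite and the acceptance script choose these sizes:

* Verification: the full 11-subject cohort at 4000 vertices, all four
  angles (44 experiments); every per-axis detection within 0.5° of truth
  and per-axis mean signed error within ±0.2°.
* Validation design count: the full 11 × 11 × 4 = 484-experiment
  enumeration, run at reduced mesh resolution (600 vertices) since only
  the design is under test.
* Growth-corrected accuracy and natural-torsion recovery: a 4-subject
  cohort at full resolution with a single 10° tri-axial twist
  (16 baselines + 16 twisted assessments); per-subject torsion recovered
  within 1°, mean absolute normalized error below 10%, coefficient of
  variance below 12%.
* The acceptance script runs verification at the full design and
  validation on a 5-subject sub-cohort (25 baselines + 100 twisted
  assessments), reporting the same metrics.
* Rigid-recovery: 20 seeded random similarities (rotation ≤ 25°, scale
  0.8–1.6) recovered within 0.1° and 0.1% scale.

## Known limitations

* The measure reports the *total* rotation between the two chosen sections;
  torsional change that is non-uniformly distributed along the shaft would
  need multi-level sectioning.
* Multi-start registration is robust for twists up to roughly ±40° of
  azimuth and ±24° of tilt — beyond the grid that candidate starts span,
  condylar aliasing can in principle win.
* The Euler decomposition is flagged, not repaired, in the gimbal-lock
  region (|pitch| within numerical reach of 90°); the rotation-vector
  components remain well-defined there.
* Principal-frame anchoring assumes a femur-like proximal asymmetry; for
  other long bones the `proximal_hint` argument and a suitable transverse
  anchor should be supplied or checked.
* Runtime is dominated by nearest-surface queries; one full assessment of a
  4000-vertex pair takes a few seconds on one core.
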