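---
title: "Estimating body segment parameters from surface scans with convex hulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating body segment parameters from surface scans with convex hulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodyhull)
```

## The problem

Inverse-dynamic analysis of human movement needs, for every body segment, its
mass, centre of mass (CoM) and inertia tensor — the body segment parameters
(BSP). These cannot be measured directly on living subjects. Regression
models transfer poorly across populations, and MRI/CT pipelines are costly.
A photogrammetric body scanner produces something much cheaper: an unordered
3D point cloud of the subject's skin surface. `bodyhull` implements the
downstream half of that workflow — everything between a scaled, landmark
annotated point cloud and a per-segment BSP table.

The estimator is geometric:

1. **Segmentation.** The world-frame cloud is cut into anatomical segments by
   half-space constraints built from named landmarks (a landmark on the
   plane, a landmark pair for the normal). Configurations are data, not
   code: the shipped default has the 14 segments commonly reported (head,
   trunk, and left/right upper arm, forearm, hand, thigh, shank, foot).
2. **Hulling.** Each segment cloud is replaced by its minimum convex hull, a
   watertight triangle mesh. Convex hulling is deliberately chosen over
   concave meshing: it needs no tuning parameters, runs unattended, and is
   insensitive to moderate gaps in the cloud. Its one systematic defect is
   that it can only *over*estimate the volume of a concave shape.
3. **Subdivision.** For segments with strong curvature the overestimation is
   reduced by cutting the segment cloud with planes perpendicular to its
   longitudinal axis (default: one mid-length cut for foot, shank, forearm
   and hand), hulling each part, and recombining the parts' mass properties
   with the parallel-axis theorem. Because each part hull is contained in
   the whole-segment hull, subdivision can only shrink the total hull
   volume, and it never undercuts the true solid.
4. **Mass properties.** For each (part) hull, volume, CoM and the full
   inertia tensor are integrated *exactly* by signed-tetrahedron
   decomposition (see below), then multiplied by the segment density:
   940 kg/m³ for the trunk — a deliberately low value so that the air in the
   lungs is part of the enclosed volume — and 1000 kg/m³ for all other
   segments by default.
5. **Mass closure.** The hull-derived total never equals the measured body
   mass, so one pro-rata factor
   $s = m_{\text{subject}} / \sum_i m_{\text{hull},i}$
   rescales every segment. Because $s$ is effectively a density correction,
   it is applied to each segment's mass *and* to its full inertia tensor
   (moments and products alike). Reported volumes stay unscaled. A useful
   identity follows: if every hull volume were inflated by the same factor,
   the final masses would still be exact — pro-rata closure cancels shared
   overestimation and only the *spread* of per-segment hull errors matters.
6. **Reporting.** The CoM is expressed the way anthropometric tables expect
   it: position along the anatomical longitudinal axis as a percentage of
   segment length from the proximal landmark, plus the transverse shift
   (also % of segment length). The longitudinal axis is +z for all segments
   except the foot, whose longitudinal axis is +x (heel to toe). Mirror
   symmetry makes left/right lateral shifts opposite in sign.

The feet of shod subjects carry an extra multiplicative correction
(`foot_factor`, default 0.51) applied to volume, mass and inertia *before*
the closure factor is computed, so that $s$ reflects corrected masses and
the reported masses still sum exactly to body mass. For barefoot scans set
`foot_factor = 1`.

## Exact polyhedral integration

`mass_properties()` decomposes the solid bounded by a watertight,
outward-wound triangle mesh into signed tetrahedra with a common apex. For a
face $(a, b, c)$ the tetrahedron $(0, a, b, c)$ contributes $\det J / 6$ to
the volume ($J = [a\,b\,c]$), $\det J\,(a+b+c)/24$ to the first moments, and

$$\int_T x_i x_j \, dV = \frac{\det J}{120}\left(s s^\top + a a^\top +
b b^\top + c c^\top\right)_{ij}, \qquad s = a + b + c,$$

to the second moments; signs cancel so that only the enclosed solid
remains. The inertia tensor about the CoM follows as
$I = \rho(\operatorname{tr}(S)\,\mathrm{Id} - S)$ shifted by the
parallel-axis theorem. These are polynomial identities, so the integrals
are exact up to floating point; the validation suite checks them to
$10^{-9}$ relative against closed forms (cube, tetrahedron) and to 1–2 %
against an independent $10^6$-sample Monte-Carlo integrator on random
polytopes.

Numerical choices:

* **Conditioning.** The mesh is translated to its vertex centroid before
  integration and the results translated back, making the output invariant
  (to $10^{-9}$ relative, tested) under arbitrary coordinate offsets.
* **Tensor convention.** Products of inertia are stored signed as the
  off-diagonals of $I = \int \rho (\lVert r\rVert^2 \mathrm{Id} - r
  r^\top)\,dV$, i.e. $I_{xy} = -\int \rho x y\, dV$. Report writers emit the
  unsigned magnitudes alongside. Everything internal is SI (m, kg, kg m²);
  any display rescaling (e.g. $10^{-4}$ kg m² ticks on plots) is left to the
  caller, because mixing scales inside the pipeline invites silent errors.
* **Watertightness** is a purely combinatorial check (every directed edge
  matched by exactly one reverse edge): hulls are combinatorially clean by
  construction, so no geometric epsilon is involved.
* **Degenerate inputs** (fewer than four points; collinear or coplanar
  clouds) raise classed errors rather than returning zero volume — a silent
  zero would corrupt the closure factor for every other segment.
* **Tie-break.** A point exactly on a cutting plane belongs to the segment
  whose configured half-space is closed; shipped configurations give the
  boundary of each transverse joint cut to the proximal (more cranial)
  segment. This makes segmentation a deterministic partition.

The convex hull itself is computed by a quickhull implementation in
compiled code (adjacency-aware horizon walking, outside-set partitioning,
tolerance $10^{-10}\times$ the cloud extent), with an optional O(n·faces)
containment audit used in tests.  One degeneracy deserves a note: point
clouds containing large exactly-coplanar clusters (e.g. the flat end caps
of sampled cylinders) can leave *micro-folds* in the triangulation —
the mesh stays watertight and the divergence-theorem volume is correct to
$\lesssim 10^{-4}$ relative, but a folded facet's plane is not a supporting
plane of the solid.  Half-space containment tests (the audit, the
Monte-Carlo integrator) therefore first restrict themselves to verified
supporting planes, those below which every hull vertex lies to within
roundoff; this plays the role that facet merging plays in qhull, applied on
the consumer side.

## The synthetic humanoid: what it does and does not emulate

Real validation data (whole-body scans with manual segmentation) cannot ship
with a package, so `generate_default_humanoid()` builds a 16-segment
humanoid from primitive solids with closed-form ground truth: a spherical
head, the trunk as three stacked elliptical cylinders sharing one
cross-section (so the whole trunk remains convex), truncated-cone limbs, an
ellipsoidal hand, and an elliptical-cylinder foot with x as its longitudinal
axis. All dimensions are fixed fractions of stature chosen to give
realistic segment mass fractions (trunk ≈ 52 %, thigh ≈ 8.7 %, upper arm
≈ 3.6 %, hand ≈ 0.6 % of body mass); densities start at 940/1000 kg/m³ and
are rescaled by one factor so the true masses sum exactly to the requested
body mass. The pose is standing, arms abducted horizontally, so every joint
admits a plane cut; primitives are pulled back ≈ 0.004 × height from each
limb joint plane so no sampled point falls exactly on a cut and no segment
inherits a neighbour's end cap.

Surface sampling is area-weighted per face/patch, optionally with isotropic
Gaussian noise and with a contiguous "hole" patch removed (the
`hole_fraction`·n points nearest a random surface location) to emulate
reconstruction gaps. All randomness flows through one explicit seed.

Concave anatomy — the curvature of shank and forearm that drives hull
overestimation — is emulated by a `bent_cylinder`: a disc swept along a
circular arc. By Pappus its volume equals the straight cylinder's
($\pi r^2 L$), its CoM has a closed form, and its inertia comes from a
documented voxel integrator (1 mm default resolution) because no practical
closed form exists; those values are flagged approximate. On this solid the
pipeline reproduces the qualitative signature of hull overestimation: the
whole-segment hull overestimates the true volume by ≈ 44 % (r = 0.04 m,
L = 0.4 m, 60° bend), one mid-length cut reduces this to ≈ 11 %, and deeper
subdivisions shrink it monotonically — the same direction of improvement
that motivates subdividing curved segments on real scans.

What the generator does **not** emulate: skin deformation and clothing,
non-standing poses, landmark placement error, scanner noise correlated with
surface texture, and the photogrammetric reconstruction itself. Passing the
synthetic-recovery tests therefore certifies the *geometry and algebra* of
the pipeline (segmentation, hulling, integration, closure), not the
upstream scanning accuracy on real bodies.

## Validation problem sizes

The test-suite and the acceptance script use: 20 000 surface points per
segment (noise-free, convex variants) for parameter recovery, where segment
masses come back within 0.2 % relative, longitudinal CoM within 0.05
percentage points and principal moments within 0.5 %; 20 seeded random
polytopes against a $10^6$-sample Monte-Carlo integrator; 100 random mass
budgets for the closure identity (residual at machine precision); and a
15 000-point bent cylinder against a 1 mm voxel reference for the
subdivision study. These sizes keep the full validation run to about a
minute while leaving each tolerance dominated by the method, not by
sampling noise.

## Known limitations

* **Holes are only cheaply tolerated when small.** For a convex solid the
  hull of a sample missing a contiguous area-fraction-$f$ cap loses the
  spherical-cap volume fraction $f^2(3 - 2f)$: ≈ 0.7 % at $f = 0.05$,
  ≈ 2.8 % at $f = 0.1$, but ≈ 10 % at $f = 0.2$. Robustness claims for
  convex hulling hold for the gap sizes typical of multi-camera coverage
  (a few percent of the surface), not for losing a fifth of a segment's
  surface in one patch; the suite asserts the closed form rather than
  pretending larger holes are free.
* Convex hulls cannot represent concavities at all; subdivision reduces but
  never eliminates the bias, and strongly curved or spread-fingered hands
  remain the worst case.
* The CoM transverse shifts are only as meaningful as the anatomical axis
  definition: they are measured from the proximal–distal landmark line,
  which itself carries placement uncertainty on real scans.
* Segment densities are two constants by default; population- or
  segment-specific density tables can be supplied through the segmentation
  configuration but are not bundled.
* Reported volumes are the unscaled (foot-corrected) hull volumes; the
  closure factor $s$ is applied to masses and inertia only, and this choice
  is recorded in every report header.
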