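---
title: "Measuring talar trochlea curvature from surface meshes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring talar trochlea curvature from surface meshes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trochlea)
```

## The measurement problem

The talar trochlea — the pulley-shaped superior articular surface of the
talus — is approximately a cylinder whose radius of curvature varies between
its medial and lateral crests and between its anterior and posterior halves.
Quantifying these regional radii from CT-derived surface meshes matters for
total ankle replacement and talar prosthesis design, where implant articular
geometry must match the native joint.

This package implements a landmark-driven measurement chain:

1. **Standardization.** Seven digitized landmarks (four trochlear corner
   edges: AM, PM, AL, PL; three border extremes: the most anterior points of
   the medial and lateral borders and the most posterior point of the medial
   border) define a transverse datum plane through the three border
   extremes, a coronal plane perpendicular to it through two border
   midpoints, and a talar centerpoint obtained by projecting the corner-edge
   chord midpoint onto the surface and circumscribing a circle through the
   three construction points. The specimen is rigidly mapped so that the
   centerpoint is the origin, +Z is superior (transverse normal), +Y
   anterior (coronal normal), and +X lateral.
2. **Stations and tops.** Six coronal planes (normal +Y) pass through the
   anteroposterior positions of the four corner edges and the two per-crest
   midpoints. On each section curve, the *top point* is the point of
   maximal Z on the relevant half (X < 0 medial, X > 0 lateral).
3. **Regional radii.** For each of AM, PM, AL, PL, a nearly sagittal section
   plane passes through the two bounding tops and the superior projection of
   their chord midpoint. The radius is the circumradius of the two tops and
   the arc-length midpoint of the section curve between them
   (R = abc / 4K for a triangle with sides a, b, c and area K). The
   mid-anterior and mid-posterior radii come from the mid-sagittal profile
   (X = 0) through its anterior, superior and posterior extreme points.
4. **Cylinder fit.** The trochlear patch (vertices inside the corner-edge
   quadrilateral with superior-facing normals) is fitted with a five-
   parameter least-squares cylinder, minimizing the squared deviations of
   point-to-axis distances from the radius.

All lengths are millimetres end to end.

## Interpreting the coordinate-system construction

Two aspects of the construction are genuinely open and were decided as
follows:

* **The station sections are coronal.** The six station planes are taken
  perpendicular to the anteroposterior axis. The alternative reading
  (parallel to the sagittal ZY plane) is geometrically degenerate: the AM
  and PM corners lie at nearly the same mediolateral position, so sagittal
  stations would coincide in pairs and could not produce six distinct
  sections, nor would the subsequent regional sections be "nearly
  sagittal".
* **The centerpoint is the world origin.** The intersection of the three
  datum planes and the circumcenter of the centerpoint construction are
  distinct points in general; the fitted centerpoint (the circle center) is
  used as the origin, and the sagittal plane is positioned through it. The
  projection that creates the third construction point runs along the
  transverse normal, superior sense — the only direction defined at that
  stage.
* **Side handling.** Left tali are mirrored about the sagittal plane during
  standardization so that medial is always at X < 0. All reported radii are
  mirror-invariant, so pooling left and right needs no further correction.
  With `side = "auto"` the side is detected from which half the medial
  landmarks land on.

## The synthetic trochlea generator

No raw meshes ship with the package; validation rests on
`generate_trochlea()`, which builds an analytic trochlea-like surface with
exactly known regional radii:

* At mediolateral station x, the sagittal profile is **two circular arcs
  tangent at their apex**, with the anterior radius interpolated linearly
  from the medial crest value to the lateral crest value (likewise
  posterior). Tangency at the apex makes the profile C1; the apex sits at
  the anteroposterior midpoint of the profile so the arc-length midpoints
  sampled by the measurement chain stay on a single arc, keeping ground
  truth exact.
* The apex height dips quadratically by the **groove depth** between the
  crests; a wedge widening of the anterior border keeps the border from
  being parallel to a coordinate plane.
* A thin **skirt** falls from each crest to a level rim emulating the
  articular margin; the three border-extreme landmarks lie on this rim.
  Because the rim is level, the transverse plane built from them is exactly
  horizontal in generator coordinates, which makes the generator's declared
  radii exact for the standardized measurement chain (the residual frame
  rotation is in-plane and affects the measured radii only through the
  mediolateral interpolation of the crest radii — below 1.5% at the default
  geometry).
* Crest radii default to 16/34 mm (medial anterior/posterior) and
  22/28 mm (lateral), the anatomically motivated configuration in which
  each posterior radius exceeds its anterior radius; anteroposterior extent
  24 mm, crest separation 26 mm, groove depth 2.5 mm — dimensions in the
  range reported for adult tali.
* The mid-sagittal profile radii are **the mediolateral blends** of the
  crest radii: MA = (AM + AL)/2 and MP = (PM + PL)/2 by construction. This
  is a structural property of the generator, with a consequence discussed
  under *Limitations*.

`generate_cylinder_patch()` provides the exact end-to-end oracle: a patch of
a right circular cylinder (axis mediolateral) for which every regional
radius and the cylinder-fit radius equal the construction radius. The
default arc sampling (about 0.33 degrees per segment) keeps the polyline
chord error small enough that three-point circle measurements recover the
radius to better than 1e-4 relative.

What the generator does **not** emulate: real segmentation noise and mesh
irregularity (vertex noise is Gaussian and isotropic), anatomical variation
in groove shape along the anteroposterior axis, non-circular (elliptical or
biarc) crest profiles, and the talar body below the articular skirt.
Passing the recovery suite therefore shows the measurement chain is correct
and well-conditioned on trochlea-like geometry, not that segmentation
artifacts in real CT meshes are harmless.

## The statistics layer

Published morphometric cohorts are summarized as (n, mean, SD) triplets, so
the test layer operates directly on summaries:

* pooled-variance (Student) two-sample t — this, and not Welch, reproduces
  the published sex and side statistics from the printed summaries;
* one-way ANOVA from summaries (SSB from count-weighted means, SSW from
  within-group variances), treating the six areas as independent groups —
  the only model that reproduces the published F = 54.905 from the printed
  table;
* Fisher's LSD pairwise comparisons on the ANOVA's mean square within,
  unadjusted by definition (a Bonferroni option exists, off by default);
* count-weighted pooling with the total-sum-of-squares variance identity;
* paired t and Pearson correlation for raw records.

Two published group sizes (male/female talus counts) are not printed
anywhere; the bundled reference file reconstructs them (37/54) as the unique
split of 91 consistent with the published t statistic, and flags them as
reconstructed.

`cohort_report()` reproduces the cohort workflow on per-specimen records:
per-area summaries under a grouping (sex, side, or an age split at the
cohort median by default), pooled t per area, paired t across sides within
bilateral subjects, and the age correlation of the fitted radius, overall
and stratified by sex.

## Synthetic cohorts and the ordering experiment

`make_synthetic_cohort()` draws subjects with the demographics of the
published cohort (28 male / 33 female subjects, about half bilateral,
ages ~14-69 with median near 38) and produces either per-specimen **records**
(regional radii drawn from an effect profile, regions modelled
independently, bilateral specimens sharing a subject-level effect that
carries 60% of the between-specimen SD) or actual **meshes** plus a
manifest for the full pipeline.

The `"ordered"` profile encodes the published ranking
PM > PL > MP > AL > MA > AM with adjacent gaps of 5 mm and SDs of
3.1-6 mm. The gap size comes from a power argument at the study size:
with 91 tali of which 30 pairs are bilateral, the subject-level effect
inflates the variance of a group mean by a factor of about 1.24, so an
adjacent LSD statistic is distributed roughly N(gap/se, 1.4) with
se ≈ sp·sqrt(2/91) ≈ 0.66 mm. Gaps of 5 mm put the expected statistic near
7.5 and the probability of any adjacent comparison missing α = 0.05 below
1e-3 for the whole chain; 4 mm gaps would leave a non-negligible failure
probability purely from sampling. These are design-time choices, fixed
once.

## Numerical choices

* **Tolerances.** Section-curve chaining and plane-membership use 1e-9 mm;
  landmark-to-surface validation allows 2 mm (digitization error exists,
  gross mislabels must fail); endpoint snapping onto section curves allows
  0.5 mm and uses *orthogonal projection onto the polyline* rather than
  nearest-vertex snapping — nearest-vertex is unstable when a point falls
  midway between two polyline vertices. Top-point ties within 1e-9 mm
  resolve toward the groove (smaller |X|), which makes flat (cylindrical)
  sections deterministic.
* **Patch separation.** The corner quadrilateral is applied with a 1e-6 mm
  boundary tolerance because structured meshes place many vertices exactly
  on its edges; without the tolerance, patch membership of those vertices
  would depend on roundoff.
* **Cylinder fit.** Five parameters (axis direction as two spherical
  angles, axis point in the plane through the centroid perpendicular to the
  axis, radius), Levenberg-Marquardt with the point cloud normalized to
  unit RMS scale, initialized along +X (the anatomical expectation) with
  the radius at the mean axis distance, restarted until stationary. The
  normalization makes the optimization exactly scale-equivariant; restarts
  polish away the solver's tendency to stop just short in the flat
  radius/axis-offset valley of shallow patches.
* **Degenerate inputs** are errors, not silent fallbacks: collinear plane
  triplets, coincident construction midpoints, projection rays that miss
  the surface, empty patches, and stations whose corners coincide
  anteroposteriorly all raise geometry errors; in batch runs these abort
  the affected specimen only, with the reason logged.
* **Reproducibility floors.** The six section radii are closed-form and
  reproduce under rigid motions to ~1e-8 mm and under scaling to ~1e-14
  relative. The cylinder radius is an iterative estimate whose objective
  is flat enough that machine-precision input perturbations move the
  optimum by up to ~2e-9 relative — a floating-point resolution floor, not
  a convergence failure; under power-of-two scaling (where the input
  scaling itself is exact in floating point) it reproduces exactly.

## Validation problem sizes

The shipped tests run the full chain on 200 x 200-vertex synthetic
trochleae (five specimens, mixed sides and radii), cylinder patches at
three radii spanning the published fitted-radius range, a 91-talus records
cohort for the ordering experiment, a small mesh-level cohort measured end
to end, and 1000-replicate null simulations for test calibration. A single
200 x 200 specimen measures in about one second.

## Limitations

* **The mid-sagittal blend constraint.** Because the generator's
  mid-sagittal profile is the mediolateral blend of the crest profiles,
  its MP radius always lies between the PM and PL radii; no mesh cohort
  built from this generator can reproduce a ranking in which PL exceeds MP.
  Real tali can (the groove has curvature of its own), and the published
  cohort does. The ordering experiment therefore runs on records-level
  cohorts, where regions are modelled independently; mesh-level cohorts
  validate measurement accuracy, not between-region cohort structure.
* Mesh-level cohorts moderate the crest-radius spread (SD capped at 2 mm):
  the two-crest model requires each crest to remain locally maximal, which
  extreme draws — plausible as *measured* values on degenerate near-flat
  arcs, but not as crest radii — would violate.
* The measured radii quantify three-point circle fits of section curves,
  which is the published protocol but is sensitive to near-flat arcs: a
  almost-straight posterior section yields a very large, poorly conditioned
  radius. The cylinder fit is the robust summary.
* Landmarks are inputs; no automatic landmark detection is attempted.
* Statistical recomputation from printed summaries inherits the 2-decimal
  rounding of those summaries (about 0.1-1% on the reproduced statistics).
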