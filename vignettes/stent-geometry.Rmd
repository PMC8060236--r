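---
title: "Centerline-based geometry of bridging stents after B-EVAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centerline-based geometry of bridging stents after B-EVAR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Branched endovascular aortic repair (B-EVAR) bridges each visceral or
renal target vessel to a cuff of the aortic main-body endograft with a
covered "bridging" stent.  How that stent sits once deployed — how
sharply the target vessel takes off from the aorta, whether the lumen
stays circular or collapses eccentrically ("kinking"), and how much the
deployed stent falls short of its labeled length — is prognostic for
branch occlusion and reintervention, and differs between self-expanding
devices (Fluency, Covera) and balloon-expandable ones (VBX).

`stentgeom` implements that geometric analysis as a reusable,
self-validating pipeline.  All measurements are taken along the lumen
centerline:

* **Take-off angle (TOA)** — the angle of the target-vessel origin from
  the aorta, on a 0–180° scale where 0° is the most acute take-off and
  180° a straight (caudally parallel) course.
* **Shape index (SI)** — per cross-section, the ratio of minimum to
  maximum diameter of the lumen contour cut perpendicular to the
  centerline.  SI = 1 is perfectly circular; low SI flags eccentric
  collapse.
* **Zone decomposition** — the stent is split at two landmarks into
  zone 1 (inside the main-body cuff), zone 2 (crossing the aneurysm sac)
  and zone 3 (inside the native target vessel), each summarized by its
  centerline length and mean SI.
* **Longitudinal shortening** — `100 · (nominal − measured) / nominal`,
  the percentage deficit of the deployed centerline length against the
  labeled stent length; only meaningful for single-stent implantations,
  and suppressed otherwise (multi-stent constructs are measured over the
  union of their arclength intervals, with overlap reported separately
  via `multi_stent_length()`).

Because no patient imaging ships with the package, every quantity is
validated on **synthetic phantoms with analytically known ground truth**:
tubular meshes swept along programmable centerlines, rasterized into
voxel label maps that stand in for segmented CTA.

## Conventions and their rationale

**TOA vector convention.**  The clinical definition of TOA is pictorial,
so the package fixes one convention and shares it between the generator
and the measurement: the angle between (a) the parent centerline tangent
at the branch origin, oriented *cranially* (toward the parent's first
point), and (b) the mean branch take-off direction, taken as the chord
over the first `window_mm` (default 5 mm) of branch arclength.  Under
this convention a caudally parallel branch reads 180° ("straight") and a
cranially recurving branch reads near 0° ("most acute").  A chord over a
window, rather than a single-point tangent, is used because the
first millimetres of an extracted centerline are the noisiest; the
window is configurable.

**Diameter definition.**  "Minimum and maximum diameter" of a section is
interpreted as the minimum and maximum *Feret (caliper) diameters* of the
contour, computed exactly on the convex hull (rotating calipers).  This
is the standard eccentricity measure, is well defined for non-convex
kinked lumens, and equals the axis lengths 2b/2a on an ellipse, so SI
reduces to b/a there.  The alternative — chords through the section's
centerline point, `chord_diameters()` — is available behind
`si_definition = "chord"` for sensitivity analysis.

**Zone intervals.**  Zones are half-open, `[0, cuff_end)`,
`[cuff_end, vessel_origin)`, `[vessel_origin, total]`, so the three zone
lengths always sum *exactly* to the total centerline length and a section
falling on a boundary is counted once, in the downstream zone.  Zone
landmarks are **inputs** (annotations/config), not detected: clinical
practice identifies them visually on CTA and no robust detection rule
exists, so the package treats them the same way the generator does — as
known arclengths.

**Per-zone SI aggregate.**  The arithmetic mean of section SI over the
zone.  (Whether clinical reports use a mean or another aggregate is not
standardized; the mean is the simplest choice consistent with
mean ± SD reporting.)

## Centerline extraction

Clinical pipelines use commercial or VMTK centerlines; this package
re-implements the function rather than wrapping those tools.  The
algorithm is a minimal-cost path on the 26-connected voxel graph of the
segmented lumen with edge cost

    step length / r^p,   p = 2,

where `r` is the Euclidean distance-transform value (distance to the
lumen boundary, computed exactly by the Felzenszwalb–Huttenlocher
separable algorithm in C++).  The `r^-p` weighting pulls the path onto
the ridge of maximal inscribed spheres — the discrete analogue of the
Voronoi-based centerline — while remaining simple and exactly testable
at phantom scale.  The raw voxel path is then smoothed (moving average,
window 5 samples, endpoints anchored at the exact source/target points)
and resampled at 0.5 mm; smoothing and resampling are applied twice
because a single pass leaves sub-voxel zigzag that measurably inflates
arclength when the lumen axis is oblique to the grid.  Source and target
come from configuration or phantom annotations; endpoints that rasterize
just outside the label (e.g. a cap center) snap to the nearest interior
voxel within 2 voxels.

Validated behaviour on 0.5 mm voxelizations: straight-tube length exact
to well under 1 %, quarter-arc (bend radius 20 mm) to 1.5 %, one-turn
helix to 2 %, and the extracted path stays within one voxel spacing of
the generating curve for bend radii above ~3 tube radii.  Tighter bends
progressively undercut the arc (the inscribed-sphere ridge itself
flattens), which is the main known limitation.

## The phantom generator

`phantom_spec()` describes a tube by a dense centerline polyline plus
per-arclength profiles of mean radius, SI and optional twist; the
elliptical section with mean radius `r` and SI `e` has semi-axes
`a = 2r/(1+e)`, `b = 2re/(1+e)`, so `(a+b)/2 = r` and `b/a = e`.
`make_tube_mesh()` sweeps that ellipse along the curve using a
**parallel-transport frame** — propagated by the minimal rotation
between successive tangents — which, unlike the Frenet frame, does not
flip at inflection points and is stable on straight segments.  Meshes
are watertight by construction (quad strips plus cap fans) and refuse to
build when the semi-major axis exceeds the local curvature radius
(self-intersection).  Default resolution: 2 sections/mm, 64 vertices per
section.

`make_branched_phantom()` attaches straight branch tubes to a parent at
configurable origin arclength, take-off angle and azimuth.  Branch and
parent are individually watertight components of one labelled mesh; the
rasterizer fills each component by even-odd in-polygon tests on planar
slices and ORs the fills, so the union needs no boolean surface
operations.  Each branch's ground truth records the constructed TOA
(recomputed from the actual direction vectors), the zone lengths implied
by its landmarks, and its nominal length, making the phantom a complete
oracle for the measurement pipeline.  `inject_kink()` blends a
raised-cosine SI dip into a spec to emulate localized kinking.

`voxelize()` rasterizes at voxel centers; `labelmap_to_surface()`
recovers a closed surface by marching tetrahedra at the 0.5 iso-level of
the 3×3×3-box-smoothed occupancy (the smoothing provides a sub-voxel
partial-volume estimate; without it, mid-voxel facets overestimate
surface area).  Label maps round-trip through NIfTI with the affine
restricted to axis-aligned form — oblique or sheared affines are
rejected rather than silently resampled, because angles and lengths in
millimetres must be unambiguous.

What the phantoms deliberately do **not** emulate: imaging physics (no
Hounsfield units, noise, or contrast), strut-level stent geometry,
motion artefacts, or segmentation error beyond rasterization.  Passing
tests therefore demonstrate correctness of the *geometry processing*,
not robustness to real CTA segmentation quality.

## The synthetic cohort

`simulate_cohort()` draws per-vessel records from a factorial
vessel-type × stent-type design with truncated-Gaussian effect models
(`beva_effect_model()`), truncation keeping SI in (0, 1], angles in
[0, 180] and lengths positive.  The default means, SDs and cell counts
(`beva_cohort_cells()`: 38 branches — 11 CTR, 11 SMA, 8 LRA, 8 RRA;
10 Fluency, 12 Covera, 16 VBX) reproduce the reporting structure of a
published single-center B-EVAR series: renal arteries take off more
acutely pre-operatively, vessels straighten post-operatively, the
balloon-expandable VBX holds higher SI in zones 2–3 but shortens most
(~11 % vs ~5 %/~2 %).  The truncated-Gaussian choice is the simplest
model matching mean ± SD tables; measured total length is derived as
`nominal · (1 − shortening/100)` so the length columns stay mutually
consistent.  Sampling is bit-reproducible for a fixed seed and restores
the caller's RNG state.

## The statistics layer

Group comparisons follow clinical-paper practice: pooled-variance
Student t-tests (`t_test()`, Welch behind `var_equal = FALSE`), one-way
ANOVA (`one_way_anova()`), Pearson correlation (`pearson_r()`), with
`summarize_groups()` choosing t-test for two groups and ANOVA beyond —
the two agree exactly at two groups (F = t²).  Pre/post TOA is compared
with a *paired* t-test (the same vessels measured twice).  No
multiple-testing correction is applied by default, matching the
single-comparison-at-a-time reporting style of the clinical tables;
`stats::p.adjust` can of course be applied to the returned p-values.
Zero-variance degeneracies (all values equal) are flagged and reported
as p = 1, never silently dropped or fatal.

Observer reproducibility uses `icc()`, fixed to **ICC(2,1)** — two-way
random effects, absolute agreement, single measurement — computed from
the mean squares of the subjects × raters decomposition with the
McGraw–Wong F-based confidence interval.  ICC(2,1) is the conservative,
standard choice when raters are considered random and absolute agreement
(not just consistency) matters, which is the relevant notion for
interobserver measurement of the same patients.

The significance-star legend used in the summary tables ('\*' at 0.05,
'\*\*' at 0.005, '\*\*\*' below 0.005) is reproduced literally from
clinical-table convention; note the middle category is a boundary case
by construction.

## Numerical choices and degenerate inputs

* Section spacing defaults to 1 mm ("sections at given distances" is
  otherwise unspecified in clinical practice); sections within half a
  spacing of either end are skipped (cap artefacts), individual failed
  sections are skipped with a count, and a profile with > 20 % failures
  is rejected outright.
* The slicer keys intersection-segment endpoints by mesh edge, so loop
  chaining is exact (no floating-point point matching); the loop nearest
  the centerline seed is kept, which disambiguates sibling lumens near a
  junction.
* Feret diameters are exact on the convex hull; non-convex contour area
  is retained from the raw polygon.
* `resample_curve()` spaces points uniformly to machine precision and
  preserves endpoints; tangents are centered differences, one-sided at
  the ends.
* Degenerate phantom specs (repeated control points, non-positive radius,
  SI outside (0, 1]), non-watertight meshes, absent labels, disconnected
  lumens, out-of-order landmarks and non-positive lengths all fail with
  specific errors rather than propagating garbage.

## Problem sizes and reproducibility

The validation suite and the acceptance script run entirely on
synthetic data at desk scale: tubes of 40–80 mm at 0.5 mm voxel spacing
(~10⁵ voxels), 64 vertices per mesh section, five take-off angles
(60°–180°), 2 000 null-ANOVA replicates and 100 simulated-cohort
replicates at the clinical group sizes (10/12/16).  These sizes were
chosen so each validated tolerance (lengths within 1–2 %, SI within
0.02, TOA within 2°, zones within 1 mm, shortening within 0.5
percentage points) is comfortably exercised while a full run completes
in well under a minute per stage on one CPU.  Every stochastic step is
seeded; `run_study()` with a fixed config and seed produces
byte-identical CSVs.

## A worked example

```{r, eval = FALSE}
library(stentgeom)

parent <- phantom_straight(80, radius = 8)         # aortic lumen stand-in
branch <- branch_spec(origin_arclength = 40, takeoff_angle_deg = 120,
                      length = 40, radius = 3,
                      cuff_end_arclength = 10, vessel_origin_arclength = 28,
                      nominal_stent_length = 44)
ph <- make_branched_phantom(parent, list(branch))

res <- measure_branch(
  ph$mesh, branch_label = 1L,
  parent_ends = ph$parent_truth$centerline$points[c(1, 161), ],
  branch_ends = ph$branch_truths[[1]]$centerline$points[c(1, 81), ],
  cuff_end_s = 10, vessel_origin_s = 28, nominal_length = 44)

res$toa          # ~120 deg, the constructed angle
res$metrics      # zone lengths ~(10, 18, 12) mm, SI ~1, shortening ~8.7 %
plot(res$profile)
```

## Known limitations

* Centerline accuracy degrades for bends tighter than ~3 tube radii and
  for voxel spacings much above 0.5 mm; tolerances are stated per
  operation and checked only at the phantom scales above.
* The branched mesh is a labelled union of closed components, not a
  single boolean-union surface; consumers that require a manifold union
  should rasterize (the supplied rasterizer handles the union exactly).
* Landmarks are trusted inputs; no automatic cuff/ostium detection.
* Agreement with any specific clinical software's centerline or diameter
  definition cannot be verified without shared data — only internal
  consistency against phantom ground truth is claimed.
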