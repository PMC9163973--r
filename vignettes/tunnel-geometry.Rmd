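---
title: "Geometry and statistics of the safe tibial tunnel simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry and statistics of the safe tibial tunnel simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tibtunnel)
```

## The problem

In transtibial posterior cruciate ligament (PCL) reconstruction a graft is
passed through a bone tunnel drilled through the proximal tibia to the PCL's
tibial attachment. A steep tunnel reduces the "killer turn" -- the sharp graft
angulation at the posterior aperture that abrades the graft -- but an
excessively steep tunnel breaches the posterior tibial cortex and endangers
the popliteal neurovascular bundle. The quantity of interest is therefore the
**permissive safe angle (PSA)**: the largest angle between the tunnel
centreline and the medial tibial plateau plane such that a 5-mm-radius
cylinder exiting at the PCL attachment leaves the posterior cortex intact.
Two companion quantities locate the entry: the **tibial tunnel height (TTH)**,
the distance from the entry point to the plateau plane, and the **tibial
tunnel depth (TTD)**, the entry-to-exit length of the centreline.

`tibtunnel` implements this simulation end to end on parametric, synthetic
proximal-tibia meshes with exact ground truth, so that every stage --
cross-section landmarking, plateau-plane construction, the tangency solver,
and the cohort statistics -- is testable without clinical CT data.

## The model, stage by stage

### Synthetic tibia generator

The axial cross-section of the proximal tibial shaft is modelled as a rounded
right triangle, following the classical description: an oblique anteromedial
cortical flat, an anterolateral flat nearly perpendicular to the posterior
margin, a circular crest arc joining them anteriorly, and a shallow posterior
arc. The profile is extruded distally with a mild isotropic taper; the
plateau is a posteriorly sloped planar cap whose rim is blended toward a
convex (condylar) outline over the top 12 mm, since real plateau rims are
rounded while the triangular shaft shape develops distally.

The posterior metaphysis carries the structures that make the tunnel problem
nontrivial:

* a narrow **attachment fossa** (Gaussian weight, half-width about 8% of the
  posterior arc) holding the PCL attachment centre B on the cortex tangent
  plane, `attachment_depth` (7 mm) below the posterior rim;
* above B, a **retro-plateau facet** receding anteriorly (facing
  posterosuperiorly), `facet_inset` = 5 mm at the rim;
* below B, a convex **metaphyseal flare** bulging posteriorly
  (`flare_depth` = 6 mm) over the free height
  g = `attachment_facet_height` − `attachment_depth` (8.5 mm by default) and
  returning to the straight cortex at its lower corner;
* flanking the fossa, **posterior condylar prominences**
  (`condyle_depth` = 5.5 mm) that extend `condyle_drop` = 7 mm deeper than
  the fossa corner before blending into the cortex.

The corner where the flare returns to the straight cortex is the structure
that limits tunnel inclination: for a sagittal tunnel the cylinder becomes
tangent to it at `acos(r/g)` from the plateau, the same closed form realised
exactly by the slab fixture (`make_slab_fixture()`). The condylar
prominences matter for the oblique (anterolateral, and to a lesser degree
anteromedial) approaches: the drill's exit aperture is an elongated oval, and
the bone flanking the fossa must recede posteriorly out of the cylinder for
the approach to be feasible at all, while its deeper distal extent softens
the otherwise steep fall of PSA with approach obliquity.

All coordinates are millimetres in a right-knee anatomical frame (+x medial,
+y anterior, +z proximal); left knees are mirrored on input. `global_scale`
multiplies every output coordinate exactly, which makes the scale law
(`PSA` unchanged, `TTH`/`TTD` proportional) hold to floating-point accuracy
and mirrors the clinical observation that stature shifts tunnel lengths but
hardly the safe angle.

### Calibration of the defaults

The population defaults are frozen in `shape_params()` /
`population_config()` and were chosen once so that the five mean PSAs of a
default cohort fall in the 50--61 degree band reported by 3D simulation
studies of this procedure, with the anteromedial approaches steepest and the
anterolateral ones shallowest. Two choices deserve comment:

* `attachment_ml_offset` = +9 mm places the attachment slightly medial of
  the posterior midline. In this geometry the obliquity of an approach
  *reduces* its PSA (the aperture oval and the lateral corner grazing bind
  first), so the medial offset is what orders the approaches
  T2 > T1 > T3 > T4 > T5 from steepest to shallowest, the ordering reported
  clinically. It also reproduces, qualitatively, the longer anteromedial
  tunnel depths.
* the free height g = 8.5 mm sets the overall level: `acos(5/8.5) = 54`
  degrees for a sagittal tunnel, raised a few degrees by the posterior
  plateau slope (7 degrees) and the anterior lean of the tapered cortex.

The generator emulates the cross-sectional shape, the plateau slope, the
facet/flare/condyle relief, and sex- and stature-dependent size. It does
**not** emulate cortical thickness, cancellous structure, real condylar
articular surfaces, subject-specific asymmetries of the plateau, or
segmentation noise of CT meshes. Passing tests therefore validate the
*algorithms* (landmarking, plane construction, tangency solving,
measurement, statistics) and the qualitative behaviour of the method, not
the clinical means themselves, which derive from 90 undeposited CT scans.

### Cross-section landmarks and entry tracks

`slice_cross_section()` intersects the mesh with an axial plane by marching
over crossing faces and chaining intersection segments through shared mesh
edges, keeping the largest closed contour (counterclockwise). The cortical
flats are found as maximal straight runs -- vertex-to-chord deviation below
`flatness_tol` (0.25 mm), grown forward and backward so runs are maximal on
both ends -- restricted to runs whose outward normal is not posterior. The
anteromedial flat is the run more oblique to the chord joining the two
posterior run ends (the triangle base); the anterolateral flat is the one
closer to perpendicular. This classification is frame-free and reproduces
the textbook construction: the extension lines of the two flats and the
posterior tangent (the support line perpendicular to the anterolateral flat)
form a right triangle with the right angle at the anterolateral-posterior
vertex.

The five entry points are per-slice landmarks: T1 at one third and T2 at the
midpoint of the anteromedial flat (from its anterior, crest-side end), T3 at
the arc midpoint of the crest, T4 and T5 likewise on the anterolateral flat.
The anchor at the crest-side end is a deliberate choice; the classical
figures place the one-third marks toward the crest. Chaining the same
fractional position across slices (1-mm spacing, linear interpolation
between slices) yields the five entry tracks; fractional identity rather
than nearest-point chaining keeps tracks stable under taper. Because run
endpoints on a faceted mesh wobble by up to the flatness tolerance, tracks
on an exactly prismatic bone are vertical to within 0.25 mm, not exactly.

### Plane M

The medial plateau rim is the boundary of the largest-area connected region
of upward-facing surface (face normals within 45 degrees of +z), restricted
to x > 0. The rim is fit with a least-squares plane, projected, and a circle
is fit by the algebraic (Kasa) method refined by Gauss-Newton iterations on
the geometric objective. The landmarks are rim vertices: E, the highest
point of the anterior half (anterior of the circle centre); G, the highest
point of the posterior half; F, the most medial point. On an exactly flat
rim the elevations tie and the tie-break picks the most anterior/posterior
points, which keeps the construction deterministic. Plane M is the plane
through E, F and G, oriented proximally. The manual best-fit-circle
construction this replaces draws tangency points by eye; extrema after
circle-based halving are the deterministic, testable surrogate.

### Tunnel solver

The posterior cortex is sampled deterministically: every posterior-facing
face (normal within 60 degrees of −y) below plane M receives a barycentric
refinement grid sized to at least 4 points per mm², and a ball of radius
`radius + 1` mm around the exit aperture is excluded. Determinism (no RNG)
makes the sampling exactly equivariant under rigid motion and isotropic
scaling. The clearance of a candidate tunnel is the minimum over samples of
the distance to the centreline segment minus the radius; negative clearance
is a cortical breach.

Entry candidates live on the approach track, parameterised by arc length
from the proximal end -- an intrinsic parameter, so the solve commutes with
rigid motions; because tracks are z-monotone, arc length and entry height
are interchangeable. Clearance decreases as the entry moves distally
(steeper tunnels), so the solver scans coarsely (2 mm), brackets the
feasibility boundary, and bisects to 0.01 mm, returning the deepest safe
entry; the result is tangent to the cortex within `clearance_tol`
(0.05 mm). A guard detects non-monotone clearance profiles and falls back
to an exhaustive fine scan, flagging the result. The millimetre value of
"close to the posterior cortex" is not standardised anywhere; 0.05 mm is
this package's choice and is configurable.

In the slab fixture the exit aperture never meets the cortex (the surface is
absent above the corner), so the fixture solves with `exclusion_radius = 0`;
with the default ball the m = r boundary case would be masked by the
exclusion rather than reported infeasible.

### Measurement

PSA is computed in closed form as `asin(|axis . normal|)`; the classical
witness construction (plane N through the centreline perpendicular to plane
M, S the centreline-plane intersection, P on the M-N intersection line, PSA
the angle A-S-P) is built alongside and agrees with the closed form to
1e-9 degrees by construction -- it exists for parity with the figure-style
definition and for rendering. TTH is the unsigned entry-to-plane distance
(the signed value is kept as an attribute); TTD is the Euclidean entry-exit
distance. When the exit lies on plane M, `TTD * sin(PSA) = TTH` exactly; on
real output the deviation measures how far the attachment sits below the
plateau plane.

### Cohort statistics

The statistics layer is implemented from the defining formulas and
cross-checked in the tests against `stats::aov`, `stats::t.test`,
`stats::TukeyHSD` and Monte-Carlo simulation:

* one-way fixed-effects ANOVA from sums of squares;
* pooled-variance independent t tests (reports also t², the F-style value
  some reports print for two-group comparisons);
* Tukey HSD pairwise p-values (studentized range) feeding an
  insert-and-absorb compact letter display -- levels share a letter exactly
  when their pairwise p exceeds alpha;
* ICC(2,1) (two-way random, absolute agreement, single measure) with the
  conventional grading: below 0.40 poor, 0.40--0.75 fair to good, above
  0.75 excellent;
* noncentral-F power and the G*Power-style minimum sample size
  (noncentrality f²N, df = (k−1, N−k)). The effect size behind any published
  sample-size statement is rarely reported; the package default of f = 0.5
  is a documented convention, not a reconstruction.

`run_subgroup_analysis()` reproduces the standard reporting layout: sex
t tests, age-group ANOVA (16--30 / 31--45 / 46--60 years), height-group
ANOVA (<1.60 / 1.60--1.70 / >1.70 m), and the approach-wise summary with
letters. Empty subgroups are reported as NA with a warning. Tukey HSD is the
post-hoc choice behind the letters; published figures show lettered groups
without naming a procedure, and the letter function accepts any p-matrix if
a different family is preferred.

## Numerical choices

* flatness tolerance 0.25 mm (chord deviation), robust on faceted meshes;
* crest/flat boundaries by maximal straight-run growth, not curvature;
* solver scan 2 mm, bisection 0.01 mm, clearance tolerance 0.05 mm;
* posterior sampling at 4 points/mm², deterministic barycentric grids with
  face-area rounding stabilised against floating-point noise so exactly
  scaled problems sample identically;
* circle fit: Kasa initialisation, Gauss-Newton refinement to 1e-12;
* degenerate inputs (vertical tunnels, flat rims, collinear landmarks,
  zero-length flats, empty slices) raise classed conditions
  (`tibtunnel_error_*`) rather than propagating NaN.

`scale_run_config()` scales every length in a run configuration; measuring a
`global_scale = s` subject under the scaled configuration is an exact scaled
replica of the unit problem. The clinical configuration instead keeps the
drill radius at 5 mm for every subject, which is why cohort PSA retains a
slight (non-significant at n = 30) positive association with stature.

## Problem sizes

Default meshes use about 75 cross-section vertices and 53 wall levels
(~7,800 faces); posterior sampling yields 20,000--30,000 points; a solve
takes a fraction of a second and a full 30-subject cohort about two minutes
on one core. The test suite uses these sizes, with the 1,000-draw
watertightness property run at reduced mesh resolution (validity does not
depend on resolution) and a handful of full-resolution confirmations.

## Known limitations

* TTH/TTD absolute levels are only loosely anchored: published studies do
  not report their cohorts' tibial dimensions, so the generator's lengths
  are plausible rather than matched; in particular the crest-approach (T3)
  depths run longer than clinical reports, and the medial-versus-lateral
  ordering of tunnel depths is compressed relative to them.
* The single-profile extrusion cannot represent independent metaphyseal
  flare of the medial and lateral condyles, patellar tuberosity relief, or
  torsion of the shaft.
* The algorithmic "observer" is essentially deterministic; re-measuring a
  cohort with coarsened solver settings yields ICC values near 1, far above
  the 0.84--0.95 range typical of human observers -- agreement grading is
  exercised, measurement-error realism is not attempted.
* Feasibility of the shallowest entry is a solver precondition; subjects
  whose attachment free height is extreme relative to the track range are
  reported as NA rows rather than forced.

```{r example, eval = FALSE}
# a small end-to-end run
tab <- run_cohort(run_config(n = 10, seed = 1))
tidy(tab)
run_subgroup_analysis(tab)
autoplot(tab, "psa_deg")
```
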