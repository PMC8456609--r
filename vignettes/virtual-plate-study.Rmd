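---
title: "A virtual study of lateral-clavicle locking plates: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual study of lateral-clavicle locking plates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Displaced fractures of the lateral clavicle are commonly fixed with
anatomic locking plates whose lateral screw clusters differ sharply between
products: some fan the screws radially, some split them into
forward/backward-angled rows, some keep them nearly parallel. Because the
screws thread into the plate at fixed angles, the implant geometry alone
determines how many screws can be buried completely inside a small lateral
fragment, and how much of the inferior cortex — where the coracoclavicular
ligaments insert — the screw tips cover. `clavsim` rebuilds this comparison
as a fully synthetic, reproducible simulation: parametric clavicle surface
models, three plate fixtures with product-style screw fans, an automatic
"as lateral as possible" placement optimizer standing in for the surgeon,
and the equivalence/multiple-comparison statistics used to analyze the
resulting tables.

Everything runs from code; no patient imaging is used or required.

## Coordinate systems

Two right-handed orthonormal frames, both with Z running medial-to-lateral,
X anterior (volar), Y cranial:

* **Plate frame.** Three landmarks at mid-thickness — medial end point,
  lateral end point, dorsal-rim midpoint — define a basal plane. Z joins
  the end points (pointing lateral), X is the in-plane perpendicular
  pointing volar (away from the dorsal landmark), Y = Z x X points
  cranial, away from the screw tips. One sentence of the source convention
  for the third axis is self-contradictory ("perpendicular to both the X
  and Y axes"); we read it as Y being perpendicular to X and Z, which is
  the only interpretation that yields a frame.
* **Clavicle frame.** Z joins the most anterior sternoclavicular point to
  the most posterior acromioclavicular (ACJ) point; Y is the cranial
  perpendicular (disambiguated by a stored cranial hint vector, since a
  bare mesh cannot distinguish up from down); X = Y x Z; origin at the
  landmark midpoint. This follows the ISB-style recommendation for the
  clavicle.

The screw **fan angles** are projected angles between top-to-tip screw
directions: alpha between the most medial and most lateral screws in the
coronal (YZ) plane, beta between the most anterior and most posterior
screws in the sagittal (XY) plane. "Most medial/lateral" is operationalized
as the pair maximizing the projected angle (ties to the lower hole index),
which is the deterministic equivalent of reading the extremes off a
drawing; a test asserts that the maximizing pair coincides with the extreme
projected inclinations on all fixtures. Directions are kept oriented
(plate-top to tip), so no angle folding is applied.

## The synthetic clavicle generator

The generator emulates the cohort reported for the original measurement:
ten left clavicles, mean length 148 mm (range 132–167), mean midshaft
diameter 11.5 mm (range 8.9–13.6). Each bone is a watertight lofted
surface:

* **Centerline.** The classic S-shape in the axial plane: an
  anterior-convex medial bow (sagitta 10% of length) and a
  posterior-convex lateral bow (6% of length), realized as a natural cubic
  spline through the two apexes and a 55% inflection point. Two mutually
  tangent circular arcs with these sagittas and that junction are
  geometrically over-constrained, so the spline — C2-smooth, same apex
  amplitudes — is used instead.
* **Cross-sections.** Elliptical through the shaft
  (anteroposterior/craniocaudal radius ratio 1.2), blending over the
  lateral 25% into a flattened super-ellipse whose width defaults to twice
  the midshaft diameter and thickness to 0.8 x diameter, giving the flat
  lateral surface a plate seats on. A smooth seed-keyed modulation of at
  most 2% individualizes bones beyond pure size scaling.
* **Landmarks** are emitted analytically from the construction (most
  anterior sternal-end vertex, most posterior acromial-end vertex, the
  acromial end-face patch), so no landmark-detection heuristic is in the
  loop.
* **Calibration.** Because the measurement axis (clavicle frame Z) is
  slightly oblique to the construction axis, the generator iteratively
  rescales its axial and radial dimensions until the *measured* length and
  midshaft diameter match the requested parameters (within 0.05 / 0.02
  mm). The measurement conventions themselves (straight-line Z-extent for
  length; mean of the two principal extents of the 50% section for
  diameter) are declared choices — the source does not state its own.

Population sampling draws lengths and diameters independently from normal
distributions centered on the reported means with sd = range/4, truncated
to the reported ranges: the simplest distribution consistent with a mean
and a range. What the generator does **not** model: cortical vs trabecular
bone, sex-specific shape beyond size, real anatomical variation modes
(it is not a statistical shape model). Tests passing on these bones
demonstrate the pipeline's correctness and the implant geometry's
consequences, not clinical performance on real anatomies.

## The plate fixtures

Three fixtures mirror the compared implant families: `distal_radial_8`
(eight radially arranged lateral screws), `lateral_extension_6` (two rows
of three, angled 19 degrees forward/backward), and `straight_6` (six
near-parallel screws). Screw directions are fixture constants parameterized
by their coronal and sagittal inclinations from straight-down; the
per-plane projection equations then make the measured fan angles exactly
the inclination spreads, which were solved to hit the published values
(20/32, 12/38, 3/12 degrees) before the measurement code existed — the
measurement path must recover them independently. Hole order is the
covered-area polygon adjacency (index 1 = most medial/anterior, tracing
the hole loop), and entry points follow the product layouts: a radial ring
for the 8-screw plate, 2 x 3 grids for the others. Plate bodies are 2
mm-thick lofted slabs with a gentle built-in axial-plane contour (6 mm
sagitta) following the hole line, as pre-contoured lateral clavicle plates
are manufactured; a perfectly straight slab cannot keep its shaft over the
clavicle's lateral bow. Screw threads, locking-hole mechanics, and
variable-angle sleeves are out of scope.

## Automatic placement

The original placements were interactive; `clavsim` replaces the surgeon
with a transparent optimization over the six rigid degrees of freedom:

* **Objective** = 1.0 x (RMS distance of the lateral-quarter underside
  sample points to the bone surface) + 0.5 x (ACJ-to-lateral-end distance)
  + 10 x (fraction of midline/pad-edge samples with no bone beneath them).
  The lateral-quarter-only gap term encodes "prioritize the lateral end,
  not the midshaft"; the ACJ term encodes "as far laterally as possible".
* **Hard constraints**: no plate vertex more than `acj_margin` (0.5 mm)
  lateral to the ACJ plane and the lateral end point itself medial to it;
  plate-bone interpenetration at most 0.2 mm; every underside midline
  sample and every pad-edge sample (inset from the pad boundary by the
  2 mm overhang tolerance — small rim projections are normal for a flat
  implant on a curved bone) must have bone directly beneath it.
* **Search**: Nelder-Mead from 8 seeded restarts (150 iterations each),
  run entirely in clavicle-frame coordinates so that results are exactly
  equivariant under rigid motion of the scene; constraint violations are
  penalized during search and re-verified afterwards. Everything is
  deterministic given the inputs and the config seed.

How the surgeons quantified "gap" is not recorded; the RMS-underside
definition is this package's declared operationalization.

**Examiner repeatability** is emulated, not reproduced: examiner 1 /
trial 1 is the optimizer output; the other three cells of the 2 x 2
design are constraint-checked random perturbations (Gaussian translations
of 0.4 mm SD along the clavicle axis and 0.3 mm SD transversely, 1 degree
SD rotation about a random axis through the plate's lateral end). The
sigmas are a calibration chosen so simulated repeatability lands in the
sub-1.5 mm band reported for human examiners — they are an input, not an
inference, and the human Table-1 values are explicitly not reproducible
targets. The repeatability claim the package does make is a property:
mean absolute ACJ-distance differences stay inside the 3 mm equivalence
margin with TOST p < 0.05.

## Fragment metrics

* **Screw traces** are ray casts of each screw axis: first cortex crossing
  = entry, second = exit (a bicortical convention — lateral-plate locking
  screws are clinically bicortical and no screw lengths are published),
  capped at 40 mm. Misses are recorded, not errors.
* **Containment**: a screw is "completely inserted" in a lateral fragment
  when its whole entry-to-exit segment (51 sampled points) lies on the ACJ
  side of the transverse cut plane and it has at least 2 mm of bone
  purchase (the floor excludes grazing hits). Cut planes sit 10, 15, 20,
  25, 30 mm medial to the most posterior ACJ landmark, normal to the
  clavicle Z axis.
* **Covered area**: inferior-cortex exit points (exit normal pointing
  caudal, frame-Y component below -0.2), taken in hole order, best-fit
  plane, shoelace area; a self-intersecting order falls back to the convex
  hull and is flagged. The primary reported value restricts exits to
  within 25 mm of the ACJ; the unrestricted value and a
  contained-screws-only variant are also computed, since the original
  description does not fix that choice.
* **Ligament zones**: trapezoid 8–26 mm, conoid 26–47 mm from the ACJ;
  fragment sizes map to the Craig-type ranges (within 10 mm: types 1/3;
  beyond: types 2B/5, ligament involved).

Only transverse cuts are simulated — no comminution, no oblique fracture
planes, no screw-screw collision checks.

## Statistics

* **TOST equivalence** on paired ACJ distances with a symmetric 3 mm
  margin: `p = max(P(T >= (dbar + margin)/se), P(T <= (dbar - margin)/se))`
  with n-1 degrees of freedom. The table format reports the mean
  *absolute* difference next to a t confidence interval for the *signed*
  mean difference (which is why published CIs of absolute differences can
  be negative); both a signed-difference TOST (primary) and an
  absolute-difference variant are emitted because the original analysis
  does not say which was used. Zero-variance differences degenerate to a
  0/1 decision by comparing the mean against the margin.
* **Steel-Dwass** for the contained-screw counts: pairwise tie-corrected
  mid-rank Wilcoxon statistics referenced to the studentized range with
  infinite degrees of freedom (`p = P(Q_k >= sqrt(2) |t|)`). Counts are
  discrete and heavily tied, which is exactly why the rank-based all-pairs
  procedure is the right tool here, with mid-ranks and the tie-corrected
  variance. For k = 2 the procedure collapses to the two-sided
  normal-approximation Wilcoxon test, which the tests verify to 1e-6.
* **Tukey HSD** for the covered areas: pooled within-group variance and
  the Tukey-Kramer statistic, p from the studentized range with N - k
  degrees of freedom. The studentized-range distribution itself comes from
  `stats::ptukey`; the surrounding statistics are computed from their
  definitions and verified against `stats::TukeyHSD` as an independent
  reference.

## Numerical choices

* Containment queries use generalized winding numbers (robust near edges
  and coplanar patches); optimizer inner loops use a faster ray-parity
  test and a z-pruned point-triangle distance, cross-checked in the tests
  against brute-force all-triangle sweeps in plain R.
* All lengths are mm, angles are reported in degrees (computed in
  radians); angle tolerances of 0.5 degrees in the fixture tests reflect
  the print precision of the published values.
* Default problem sizes: bone meshes with 72 axial x 20 radial segments
  (about 2,900 triangles), 200 gap sample points, 8 placement restarts.
  These were chosen as the coarsest resolutions at which the measured
  anatomy calibrates to within the tolerances above; unit tests use
  coarser, faster variants of the same constructions.
* Per-task seeds derive from the master seed via a deterministic string
  hash of (module, plate, clavicle, examiner, trial), so any record can be
  regenerated in isolation and the full study is byte-reproducible.

## Known limitations

The generator is not a statistical shape model; plate bending/contouring
to the individual bone is excluded (the built-in contour is fixed);
biomechanics — pull-out force, construct stiffness, bone quality — is
entirely out of scope; and the examiner model reproduces the *structure*
of the repeatability analysis, not human behavior. Conclusions supported
by this package are therefore about implant screw geometry interacting
with fragment size on idealized bones, which is also all the virtual
study design can claim.
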