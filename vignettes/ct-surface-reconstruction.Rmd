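---
title: "From CT slice contours to simplified surface meshes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT slice contours to simplified surface meshes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsurf)
```

# The problem

Preoperative CT of a hollow organ such as the bladder is read slice by
slice; a two-dimensional reading loses the spatial relationships that
matter for staging and for planning transurethral resection of a wall
tumor. The standard remedy is to turn the per-slice delineations into a
three-dimensional surface model. `ctsurf` implements one complete route:
per-slice contour polygons (or a signed implicit sample) are classified
into a tri-state voxel function, a modified marching-cubes pass extracts
a closed triangle surface with central-difference normals, and a
priority-driven edge-collapse pass reduces the triangle count so the
model stays interactive.

# The tri-state voxel function

Each slice carries zero or more closed polygons $L_1, \dots, L_n$. For a
voxel at position $(a, b, c)$, the function $f$ is

* $f = -1$ when the in-slice point lies outside all polygons of its
  slice (including every voxel of a slice without polygons),
* $f = 0$ when it lies on a polygon boundary, operationalized as
  within `onTolerance` millimetres of a segment,
* $f = +1$ when it lies inside.

Two readings of "inside" are offered. The default even-odd rule counts
covering polygons, so the lumen enclosed by a nested inner contour is
*outside* the wall — the behavior needed for hollow organs, where each
slice of the wall is an annulus. The literal rule ("inside at least one
polygon") is kept behind `rule = "any"` because it is the plain reading
of the classification as stated; it fills lumens and is only appropriate
for solid structures.

Numerical conventions: point-in-polygon is decided by ray casting with
the half-open edge rule, which is deterministic for points aligned with
vertices; the on-state is decided *first* via exact point-to-segment
distance, so boundary hits cannot be claimed by either side. The default
`onTolerance` is 0 mm — no tolerance is inherent to the formulation, so
with contour input the 0 state arises only from exact hits; a scanner's
in-plane resolution (typically 0.5–1 mm) is a reasonable setting when a
genuine "on the contour" band is wanted. Slices are classified
independently; no interpolation is performed between slices, because the
classification is defined per slice.

# Surface extraction

Extraction is cell-by-cell marching cubes with two deliberate
modifications and a set of fixed conventions:

* **Midpoint intersections.** A cell edge whose endpoint states have
  opposite signs is cut exactly at its midpoint. No scalar interpolation
  is attempted — the tri-state function carries no magnitude to
  interpolate. (For a binarized field this coincides with linear
  interpolation of $\pm 1$ values.)
* **Zero-state snapping.** State 0 counts as inside for the case-table
  lookup, but a crossing edge whose inside endpoint is state 0 places
  its vertex exactly on that grid point: the surface passes through
  voxels that lie on a contour line. Triangles that degenerate when two
  of their vertices snap to the same grid point are dropped. The
  alternative — a full $3^8$ ternary case table — would buy nothing: the
  two rules above reproduce the intended geometry with the standard 256
  cases.
* **Case table by construction.** The 256-entry table is generated at
  load time, not transcribed. For each corner configuration, the
  surface/cell-boundary intersection segments are derived face by face:
  walking a face counterclockwise (seen from outside), each
  inside-to-outside crossing opens a segment that closes at the next
  crossing. On the ambiguous faces (two diagonally opposite inside
  corners) this convention always keeps the two *outside* corners
  separated. Because the rule is intrinsic to the face, the two cells
  sharing a face always agree, so meshes cannot crack; the segments
  chain into closed cycles that are fan-triangulated and oriented
  outward (inside-to-outside). Complementary configurations are handled
  by the same rule applied to their own sign pattern, which is what
  keeps adjacent mixed cases consistent.
* **Welding and padding.** Vertices are shared across cells by exact
  cell-edge identity (snapped vertices by grid-point identity) — exact
  keys are available because placement is combinatorial, so no
  floating-point proximity tolerance exists to go wrong. The label
  volume is padded with a one-voxel $-1$ shell so structures touching
  the array boundary still close.

Any field with a single label yields an empty mesh; grids smaller than
$2^3$ are rejected by the class validity.

## Normals

At grid points the normal is the central difference of $f$ per axis,
e.g. $(f(a-1,b,c) - f(a+1,b,c))/2$ along the first axis — positive
toward the outside since $f$ is $+1$ inside — with one-sided differences
at the (padded) volume border. A midpoint vertex takes the equal-weight
mean of its edge's two endpoint normals; a snapped vertex takes the
grid point's own normal. Results are normalized to unit length. Where
the raw difference vanishes (possible in flat label neighborhoods) the
vertex falls back to the area-weighted mean of its incident face
normals. The mapping from vertex to generating grid points is recovered
from the coordinates themselves (they are exact half-multiples of the
spacing), so a mesh not extracted from the given field is detected and
rejected.

# The deletion algorithm

Simplification repeatedly collapses the edge $s$ with the smallest
priority

$$Y(s) = C_t\,T(s) + C_x\,X(s) + C_g\,G(s),$$

merging its endpoints at the edge midpoint.

* $T(s) \in [0, 2]$ is the flatness term: $\max\,(1 - \dot L_i \cdot
  \dot L_j)$ over all pairs of unit normals of the triangles incident to
  either endpoint. The "all incident pairs" reading (rather than only
  adjacent pairs) is the stricter one: it also penalizes saddle
  neighborhoods whose adjacent triangles happen to agree.
* $X(s) \in [0, 1]$ is the shape term: $1 - \min q$ over the triangles
  having $s$ as a side, with the isoperimetric quality
  $q = 12\sqrt{3}\,A / p^2$ ($A$ area, $p$ perimeter). The normalization
  is chosen so the anchors are meaningful — an equilateral triangle (the
  isoperimetric maximum) scores $q = 1$, hence $X = 0$, and a degenerate
  triangle scores $X = 1$. An unnormalized $A/p^2$ ratio would compress
  $X$ into $[2/3, 1]$; since the three weights are free parameters, the
  two choices differ only by a rescaling of $C_x$, and the normalized
  form keeps the documented range.
* $G(s)$ is the edge length divided by `lengthScale`, by default the
  mean edge length of the input mesh, making the three terms
  commensurable and $Y$ resolution-independent.

The formulation names the three ingredients but fixes neither the
weights nor the ordering, so both are package design choices: the
default weights are $C_t = C_x = C_g = 1$, and the *lowest* $Y$
collapses first — short, flat, well-shaped edges are exactly the ones
whose removal loses least geometry, which matches the stated goal of
simplifying for speed without visible damage.

Robustness rules: a candidate collapse is skipped when the edge is not
an interior manifold edge, when the link condition fails (the endpoints'
common neighbors must be exactly the two opposite vertices — collapsing
would otherwise pinch the surface), or when a surviving face's normal
would rotate by $90^\circ$ or more (or the face would lose its area).
Skipped edges are retried only after a collapse in their neighborhood
changes the situation. Priorities of all edges within one ring of the
surviving vertex are recomputed after every collapse — exactly the set
whose $T$, $X$, $G$ or validity can have changed — so the selection is
always globally greedy on current values; the test suite verifies this
against a brute-force oracle that recomputes every edge at every step.
Exact ties in $Y$ (common on symmetric lattice meshes) are broken by the
smallest vertex-index pair, which keeps runs reproducible. Boundary
edges of open meshes are never collapsed: the package's meshes are
closed by construction, and refusing is the one behavior that cannot
break a watertight invariant. Interior collapses remove exactly two
faces each, so a closed mesh keeps its Euler characteristic.

# Diagnostic evaluation

The evaluation layer is deliberately exact and small. With $A$ true
positives, $B$ true negatives, $C$ false positives and $D$ false
negatives: accuracy $= (A+B)/(A+B+C+D)$, specificity $= B/(C+B)$,
sensitivity $= A/(D+A)$; an empty denominator raises an error naming the
metric rather than returning `NaN`. ROC curves use the prediction rule
score $\ge$ threshold (ties predicted positive), thresholds at the
unique scores in descending order behind a $+\infty$ sentinel, and
trapezoidal AUC — which equals the tie-aware Mann–Whitney concordance
probability, a property the tests check to $10^{-12}$ against a
brute-force pairwise count.

# Synthetic phantoms: what they do and do not emulate

No imaging data ship with the package; every downstream stage is
exercised on phantoms with known ground truth.

* `makeSpherePhantom()` — closed-form volume and area; the workhorse for
  convergence and normal-fidelity checks.
* `makeBladderPhantom()` — an ellipsoidal wall shell (defaults: outer
  semi-axes $40 \times 35 \times 30$ mm, a moderately full bladder; wall
  4 mm) with seeded spherical wall lesions (default radius 5 mm)
  protruding into the lumen like papillary tumors. Lesion placement
  rejects overlaps and is fully determined by one integer seed; no
  global RNG state is touched. Ground truths have no closed form and are
  computed on a ~1 mm quadrature grid — volume from a smoothed interface
  indicator, area from the co-area formula
  $\int \delta_\epsilon(f/|\nabla f|)\,|dV|$ with a cosine mollifier of
  half-width two grid steps — and flagged `approximate` (about one
  percent at this scale, as the sphere cross-check in the tests shows).

The phantoms emulate geometry only: a labeled volume with the topology
and scale of a bladder wall. They do not simulate CT physics — noise,
partial volume, beam hardening, contrast timing — nor observer
variability in contouring. Tests passing on phantoms therefore validate
the *reconstruction machinery* (classification, topology, convergence,
simplification, determinism), not clinical segmentation accuracy, which
would require patient data that are not deposited.

One consequence for the oracle tests deserves a note. The random "blob"
fields used to compare against an independent marching-cubes
implementation are unions of spheres constrained so every pair is either
clearly separated or clearly overlapping (by at least two voxels). At
tangent contacts the discrete topology genuinely depends on the
ambiguous-case convention — reference implementations disagree *with
each other* there — so topological comparison is only meaningful on
fields whose sampling resolves the topology; the constraint encodes
that, not a preference for easy cases.

# Problem sizes and costs

The package is pure R; the case table is built once at load. The suite
and the acceptance script use grids of $32^3$–$96^3$ (a $64^3$ sphere
extraction takes well under a second; the full eight-property acceptance
run about a minute and a half) and decimate meshes of roughly 5,000
faces to 10%. Decimation is the slowest stage (about
$O(E)$ selection per collapse in plain R); meshes in the
$10^4$–$10^5$-face range remain practical, far above the sizes the
bundled phantoms produce.

# Known limitations

* Contour input assumes simple (non-self-intersecting) polygons with
  implicit closure; intersecting contours are not detected.
* The contour route classifies voxel centers only; a voxel whose center
  is inside but whose volume straddles the contour is wholly inside, so
  sub-voxel partial-volume effects are invisible.
* Midpoint placement quantizes vertex coordinates to half-grid
  positions; surface area converges more slowly than volume (the usual
  staircase overshoot) and is reported as-is.
* Simplification is greedy with midpoint placement; it optimizes no
  quadric error and will not reach the quality of error-minimizing
  placements at aggressive targets — by design, since the ranking
  function itself is the object of interest.
* NIfTI is the only volume container (spacing and origin stored in the
  sform); DICOM series and NRRD must be converted upstream.
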