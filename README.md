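# ctsurf

Contour-based three-dimensional surface reconstruction of CT volumes,
with priority-driven mesh simplification and diagnostic-evaluation
utilities. The package targets the kind of workflow used for
preoperative imaging of hollow organs — e.g. visualizing the bladder
wall and papillary tumors in non-muscle-invasive bladder cancer — where
per-slice contour lines drawn on CT slices must become a closed,
manageable triangle surface.

## What it computes

**Tri-state voxel classification.** Given closed contour polygons
L1, ..., Ln on each axial slice, every voxel (a, b, c) receives

    f(a, b, c) = -1   outside all contour lines of its slice
    f(a, b, c) =  0   on a contour line (within a distance tolerance)
    f(a, b, c) = +1   inside the contour lines

(`classifyVoxels()`; nested contours are handled by the even-odd rule so
the lumen of a hollow organ stays outside, with a literal
"inside-any-polygon" mode available). A signed implicit sample can be
classified directly with `classifyImplicit()`.

**Modified marching cubes.** `extractSurface()` sweeps the 256-case
cell table over the field. An edge whose endpoint states differ in sign
is cut at its *midpoint* — not at an interpolated position — and an edge
whose inside endpoint is state 0 passes exactly through that grid point.
Vertices are welded by exact edge identity and the volume is padded
outside, so the result is watertight whenever the structure is interior
to the grid. `vertexNormals()` attaches outward unit normals from
central differences of f,

    M = ( (f(a-1,b,c) - f(a+1,b,c))/2,
          (f(a,b-1,c) - f(a,b+1,c))/2,
          (f(a,b,c-1) - f(a,b,c+1))/2 ),

averaged onto the cut-edge midpoints.

**Deletion algorithm.** `decimateMesh()` simplifies by greedy edge
collapse ranked by the priority

    Y(s) = Ct * T(s) + Cx * X(s) + Cg * G(s)

with T(s) = max(1 - Li . Lj) over unit normals of the triangles at the
edge's endpoints (flatness), X(s) = 1 - min isoperimetric quality of
the triangles with side s (shape), and G(s) the normalized edge length.
The lowest-priority edge collapses to its midpoint; collapses that
violate the link condition or flip a face normal are skipped, so a
watertight mesh stays watertight with its Euler characteristic intact.

**Evaluation.** `confusionMetrics()` implements
accuracy = (A+B)/(A+B+C+D), specificity = B/(C+B),
sensitivity = A/(D+A) from true/false positive/negative counts, and
`rocCurve()` sweeps thresholds to an ROC curve with trapezoidal AUC.

Synthetic phantoms (`makeSpherePhantom()`, `makeBladderPhantom()`, with
analytic or fine-quadrature ground truth), per-slice contour tracing
(`contoursFromGrid()`), mesh statistics (`meshStats()`), and I/O for
NIfTI volumes, contour JSON and STL/PLY/OBJ meshes round out the
pipeline; `runPipeline()` and the `exec/ctsurf` script run it end to
end with a JSON run report.

## Worked example

```r
library(ctsurf)

ph    <- makeSpherePhantom(12)                      # radius 12 mm
g     <- voxelize(ph, dims = c(64, 64, 64),
                  spacing = rep(32/63, 3), origin = rep(-16, 3))
field <- classifyImplicit(g)
mesh  <- vertexNormals(field, extractSurface(field))
meshStats(mesh)
```

```
$nVertices           10536
$nEdges              31602
$nFaces              21068
$eulerCharacteristic 2
$watertight          TRUE
$surfaceArea         1967       # mm^2; analytic 4*pi*12^2 = 1809.6
$enclosedVolume      7226       # mm^3; analytic (4/3)*pi*12^3 = 7238.2
```

The reconstruction is closed (every edge borders two faces, V - E + F =
2) and encloses the sphere's volume to 0.17%. (The area overshoots by
the usual staircase factor of a binary midpoint surface; volume is the
converging quantity.) Simplifying to a tenth of the faces barely moves
the volume:

```r
simp <- decimateMesh(mesh, simplifyConfig(targetRatio = 0.1))
meshStats(simp)$nFaces            # 2106
meshStats(simp)$enclosedVolume    # 7160.3  (-0.9%)
```

The diagnostic layer works on plain counts and scores:

```r
confusionMetrics(confusionMatrix(A = 90, B = 80, C = 10, D = 20))
# accuracy 0.85, specificity 0.8889, sensitivity 0.8182
rocCurve(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))
# RocCurve: 5 operating points, AUC = 0.7500
```

## Vignette

`vignettes/ct-surface-reconstruction.Rmd` documents the model and its
assumptions, the numerical conventions (midpoint intersections,
ambiguous-case resolution, zero-state snapping), the priority weights,
what the synthetic phantoms do and do not emulate, and known
limitations.
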