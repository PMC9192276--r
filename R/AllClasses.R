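#' @import methods
NULL

#' Axis-aligned scalar volume
#'
#' A `VoxelGrid` holds a 3D array of scalar samples together with the
#' physical geometry of the sampling lattice. Voxel centres sit at integer
#' indices: the world position (in mm) of array element `(i, j, k)`
#' (1-based, as usual in R) is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @slot values 3D numeric array of samples; `dim(values)` is the grid size.
#' @slot spacing Numeric length-3, voxel spacing in mm along each axis; all
#'   components strictly positive.
#' @slot origin Numeric length-3, world coordinate (mm) of voxel `(1, 1, 1)`.
#'
#' @seealso [voxelize()], [classifyImplicit()], [readVolume()]
#' @export
setClass("VoxelGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 3L) return("'values' must be a 3D array")
    if (any(d < 2L)) return("all grid dimensions must be >= 2")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0)) {
      return("'spacing' must be 3 positive finite numbers")
    }
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("'origin' must be 3 finite numbers")
    TRUE
  }
)

#' Per-slice closed contour polygons
#'
#' A `ContourSet` stores, for slices taken along one grid axis, the closed
#' polygons (contour lines L1, L2, ..., Ln) outlining a structure on each
#' slice. Polygon vertices are 2D coordinates in the slice plane (world mm,
#' in the order of the two in-slice axes); the first vertex is not repeated
#' at the end (closure is implicit). Vertices are ordered counterclockwise.
#'
#' @slot sliceAxis Integer in 1:3, the axis perpendicular to the slices
#'   (3 = axial, the CT convention, is the usual choice).
#' @slot slices A list; each element is a list with fields `index` (1-based
#'   slice index along `sliceAxis`) and `polygons` (list of n x 2 numeric
#'   matrices, each with >= 3 rows).
#'
#' @seealso [contoursFromGrid()], [classifyVoxels()], [readContours()]
#' @export
setClass("ContourSet",
  representation(sliceAxis = "integer", slices = "list"),
  validity = function(object) {
    if (length(object@sliceAxis) != 1L || !object@sliceAxis %in% 1:3)
      return("'sliceAxis' must be 1, 2 or 3")
    for (sl in object@slices) {
      if (!is.list(sl) || is.null(sl$index) || is.null(sl$polygons))
        return("each slice must be a list with 'index' and 'polygons'")
      if (sl$index < 1L) return("slice indices must be >= 1")
      for (p in sl$polygons) {
        if (!is.matrix(p) || ncol(p) != 2L || nrow(p) < 3L)
          return("polygons must be n x 2 matrices with n >= 3")
        if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ]))
          return("polygon closure must be implicit (first vertex not repeated)")
      }
    }
    TRUE
  }
)

#' Tri-state voxel classification
#'
#' A `TriStateField` stores the voxel function f(a, b, c) over a grid:
#' -1 for voxels outside all contour lines of their slice, 0 for voxels
#' lying on a contour line, +1 for voxels inside. Geometry follows the
#' same convention as [VoxelGrid-class].
#'
#' @slot labels 3D integer array with values in \{-1, 0, 1\}.
#' @slot spacing Numeric length-3 voxel spacing (mm).
#' @slot origin Numeric length-3 world coordinate of voxel `(1, 1, 1)`.
#'
#' @seealso [classifyVoxels()], [classifyImplicit()], [extractSurface()]
#' @export
setClass("TriStateField",
  representation(labels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    d <- dim(object@labels)
    if (length(d) != 3L) return("'labels' must be a 3D array")
    if (any(d < 2L)) return("all grid dimensions must be >= 2")
    if (!all(object@labels %in% c(-1L, 0L, 1L)))
      return("labels must all be -1, 0 or +1")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      return("'spacing' must be 3 positive numbers")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      return("'origin' must be 3 finite numbers")
    TRUE
  }
)

#' Indexed triangle mesh
#'
#' Vertices are world coordinates in mm; faces index vertices (1-based).
#' Face winding is counterclockwise seen from outside, so face normals
#' point outward. Per-vertex unit normals are optional (a 0 x 3 matrix
#' when absent).
#'
#' @slot vertices n x 3 numeric matrix of vertex positions (mm).
#' @slot faces m x 3 integer matrix of vertex indices.
#' @slot normals n x 3 matrix of unit vertex normals, or 0 x 3 if unset.
#'
#' @seealso [extractSurface()], [decimateMesh()], [meshStats()], [writeMesh()]
#' @export
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix", normals = "matrix"),
  prototype(
    vertices = matrix(numeric(0), 0L, 3L),
    faces = matrix(integer(0), 0L, 3L),
    normals = matrix(numeric(0), 0L, 3L)
  ),
  validity = function(object) {
    if (ncol(object@vertices) != 3L) return("'vertices' must have 3 columns")
    if (ncol(object@faces) != 3L) return("'faces' must have 3 columns")
    nf <- nrow(object@faces)
    if (nf > 0L) {
      f <- object@faces
      if (any(f < 1L) || any(f > nrow(object@vertices)))
        return("face indices out of range")
      if (any(f[, 1L] == f[, 2L] | f[, 2L] == f[, 3L] | f[, 1L] == f[, 3L]))
        return("faces must not repeat a vertex index")
    }
    nn <- nrow(object@normals)
    if (nn > 0L) {
      if (nn != nrow(object@vertices))
        return("'normals' must have one row per vertex")
      len <- sqrt(rowSums(object@normals^2))
      if (any(abs(len - 1) > 1e-9))
        return("normals must have unit length (within 1e-9)")
    }
    TRUE
  }
)

#' Phantom with analytic ground truth
#'
#' A phantom is an implicit solid: `implicitFn` maps an n x 3 matrix of
#' world coordinates (mm) to a signed scalar per row, negative outside the
#' solid and positive inside. Ground-truth surface area and volume are
#' carried alongside, either closed-form (`approximate = FALSE`) or from
#' fine-grid numerical quadrature (`approximate = TRUE`).
#'
#' @slot implicitFn Function taking an n x 3 coordinate matrix, returning a
#'   numeric vector of length n.
#' @slot analyticVolume Ground-truth enclosed volume, mm^3.
#' @slot analyticArea Ground-truth boundary surface area, mm^2.
#' @slot approximate Logical; `TRUE` when the ground truths are numerical
#'   estimates rather than closed-form values.
#' @slot description Free-text label.
#'
#' @seealso [makeSpherePhantom()], [makeBladderPhantom()], [voxelize()]
#' @export
setClass("Phantom",
  representation(implicitFn = "function", analyticVolume = "numeric",
                 analyticArea = "numeric", approximate = "logical",
                 description = "character"),
  validity = function(object) {
    if (length(object@analyticVolume) != 1L || object@analyticVolume <= 0)
      return("'analyticVolume' must be a single positive number")
    if (length(object@analyticArea) != 1L || object@analyticArea <= 0)
      return("'analyticArea' must be a single positive number")
    TRUE
  }
)

#' Diagnostic confusion matrix
#'
#' Counts of diagnostic outcomes against a reference standard: `A` true
#' positives, `B` true negatives, `C` false positives, `D` false negatives.
#'
#' @slot A,B,C,D Non-negative integer counts.
#' @seealso [confusionMatrix()], [confusionMetrics()]
#' @export
setClass("ConfusionMatrix",
  representation(A = "integer", B = "integer", C = "integer", D = "integer"),
  prototype(A = 0L, B = 0L, C = 0L, D = 0L),
  validity = function(object) {
    for (s in c("A", "B", "C", "D")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v < 0L)
        return(sprintf("count '%s' must be a single non-negative integer", s))
    }
    TRUE
  }
)

#' ROC curve
#'
#' Operating points of a score-based binary classifier swept over all
#' decision thresholds (prediction rule: score >= threshold), with the
#' area under the curve computed by the trapezoidal rule.
#'
#' @slot thresholds Descending score thresholds (first is +Inf sentinel).
#' @slot fpr,tpr False/true positive rate at each threshold; nondecreasing,
#'   starting at 0 and ending at 1.
#' @slot auc Area under the curve, in `[0, 1]`.
#' @seealso [rocCurve()]
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric"),
  validity = function(object) {
    n <- length(object@thresholds)
    if (length(object@fpr) != n || length(object@tpr) != n)
      return("'thresholds', 'fpr' and 'tpr' must have equal length")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
      return("'fpr' and 'tpr' must be nondecreasing")
    if (object@auc < 0 || object@auc > 1) return("'auc' must lie in [0, 1]")
    TRUE
  }
)

#' Mesh simplification settings
#'
#' Weights of the edge-collapse priority Y(s) = Ct*T(s) + Cx*X(s) + Cg*G(s)
#' and the stopping target. T is the flatness term, X the triangle shape
#' coefficient, G the edge length divided by `lengthScale`. Exactly one of
#' `targetFaces` / `targetRatio` is set (the other is `NA`).
#'
#' @slot ct,cx,cg Non-negative term weights; at least one positive.
#' @slot targetFaces Target face count (positive integer) or `NA`.
#' @slot targetRatio Target fraction of input faces in (0, 1] or `NA`.
#' @slot lengthScale Length normalizer in mm, or `NA` to use the mean input
#'   edge length.
#' @seealso [simplifyConfig()], [decimateMesh()], [edgePriority()]
#' @export
setClass("SimplifyConfig",
  representation(ct = "numeric", cx = "numeric", cg = "numeric",
                 targetFaces = "integer", targetRatio = "numeric",
                 lengthScale = "numeric"),
  validity = function(object) {
    w <- c(object@ct, object@cx, object@cg)
    if (any(!is.finite(w)) || any(w < 0))
      return("weights ct, cx, cg must be finite and non-negative")
    if (all(w == 0)) return("at least one of ct, cx, cg must be positive")
    hasF <- !is.na(object@targetFaces)
    hasR <- !is.na(object@targetRatio)
    if (hasF == hasR)
      return("exactly one of 'targetFaces' and 'targetRatio' must be set")
    if (hasF && object@targetFaces < 4L)
      return("'targetFaces' must be >= 4")
    if (hasR && (object@targetRatio <= 0 || object@targetRatio > 1))
      return("'targetRatio' must lie in (0, 1]")
    if (!is.na(object@lengthScale) && object@lengthScale <= 0)
      return("'lengthScale' must be positive")
    TRUE
  }
)

#' Priority record for one mesh edge
#'
#' The decomposition of the deletion priority of an edge s:
#' flatness T(s) in `[0, 2]`, shape coefficient X(s) in `[0, 1]`,
#' normalized length G(s) >= 0, and Y(s) = Ct*T + Cx*X + Cg*G.
#'
#' @slot edge Integer pair, the edge's vertex indices (ascending).
#' @slot T,X,G,Y Priority terms as above.
#' @seealso [edgePriority()]
#' @export
setClass("EdgeRecord",
  representation(edge = "integer", T = "numeric", X = "numeric",
                 G = "numeric", Y = "numeric"),
  validity = function(object) {
    if (length(object@edge) != 2L) return("'edge' must be two vertex indices")
    if (object@T < -1e-12 || object@T > 2 + 1e-12) return("T must lie in [0, 2]")
    if (object@X < -1e-12 || object@X > 1 + 1e-12) return("X must lie in [0, 1]")
    if (object@G < 0) return("G must be >= 0")
    TRUE
  }
)
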