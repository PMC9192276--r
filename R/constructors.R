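#' @include AllClasses.R
NULL

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Create a VoxelGrid
#'
#' @param values 3D numeric array of samples.
#' @param spacing Numeric length-3 voxel spacing in mm (default 1 mm iso).
#' @param origin Numeric length-3 world coordinate of voxel `(1, 1, 1)`
#'   (default the world origin).
#' @return A [VoxelGrid-class].
#' @examples
#' g <- voxelGrid(array(rnorm(27), c(3, 3, 3)))
#' gridDims(g)
#' @export
voxelGrid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("VoxelGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a TriStateField
#'
#' @param labels 3D array with values in \{-1, 0, 1\}.
#' @param spacing,origin Grid geometry as in [voxelGrid()].
#' @return A [TriStateField-class].
#' @export
triStateField <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(labels) <- "integer"
  new("TriStateField", labels = labels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Create a TriMesh
#'
#' @param vertices n x 3 numeric matrix of positions (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param normals Optional n x 3 matrix of unit vertex normals.
#' @return A [TriMesh-class].
#' @examples
#' tri <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                matrix(c(1, 2, 3), 1))
#' @export
triMesh <- function(vertices, faces, normals = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L,
                     nrow = if (length(vertices)) nrow(as.matrix(vertices)) else 0L)
  if (is.null(faces) || length(faces) == 0L) {
    faces <- matrix(integer(0), 0L, 3L)
  } else {
    faces <- as.matrix(faces)
    storage.mode(faces) <- "integer"
  }
  if (is.null(normals)) normals <- matrix(numeric(0), 0L, 3L)
  new("TriMesh", vertices = vertices, faces = faces, normals = normals)
}

#' Create a ContourSet
#'
#' @param slices List of `list(index =, polygons =)` entries; see
#'   [ContourSet-class].
#' @param sliceAxis Axis perpendicular to the slices (default 3, axial).
#' @return A [ContourSet-class].
#' @export
contourSet <- function(slices, sliceAxis = 3L) {
  slices <- lapply(slices, function(s) {
    s$index <- as.integer(s$index)
    s$polygons <- lapply(s$polygons, function(p) {
      p <- as.matrix(p)
      storage.mode(p) <- "double"
      p
    })
    s
  })
  new("ContourSet", sliceAxis = as.integer(sliceAxis), slices = slices)
}

#' Create a ConfusionMatrix
#'
#' @param A True-positive count.
#' @param B True-negative count.
#' @param C False-positive count.
#' @param D False-negative count.
#' @return A [ConfusionMatrix-class].
#' @examples
#' confusionMatrix(A = 90, B = 80, C = 10, D = 20)
#' @export
confusionMatrix <- function(A, B, C, D) {
  asCount <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
      stopf("count '%s' must be a single non-negative integer", nm)
    as.integer(x)
  }
  # initialize() rather than new(): an argument named "C" would otherwise
  # partially match new()'s 'Class' formal
  initialize(new("ConfusionMatrix"), A = asCount(A, "A"), B = asCount(B, "B"),
             C = asCount(C, "C"), D = asCount(D, "D"))
}

#' Create a SimplifyConfig
#'
#' @param ct,cx,cg Non-negative weights of the flatness, shape and length
#'   terms of the collapse priority (defaults 1, 1, 1).
#' @param targetFaces Stop when the face count reaches this value.
#' @param targetRatio Alternatively, stop at this fraction of the input
#'   face count. Exactly one of `targetFaces` / `targetRatio` is given.
#' @param lengthScale Normalizer (mm) for the length term; default `NA`
#'   uses the mean edge length of the input mesh.
#' @return A [SimplifyConfig-class].
#' @examples
#' simplifyConfig(targetRatio = 0.1)
#' @export
simplifyConfig <- function(ct = 1, cx = 1, cg = 1, targetFaces = NA,
                           targetRatio = NA, lengthScale = NA) {
  new("SimplifyConfig", ct = as.numeric(ct), cx = as.numeric(cx),
      cg = as.numeric(cg), targetFaces = as.integer(targetFaces),
      targetRatio = as.numeric(targetRatio),
      lengthScale = as.numeric(lengthScale))
}

# world coordinates of the voxel (i, j, k) (rows of an index matrix)
indexToWorld <- function(idx, spacing, origin) {
  sweep(sweep(idx - 1, 2L, spacing, "*"), 2L, origin, "+")
}

# evaluate a function with a private RNG stream, leaving the caller's
# .Random.seed untouched
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
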