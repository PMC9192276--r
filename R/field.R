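#' @include constructors.R
NULL

# even-odd (ray casting, half-open edges) inside counts and minimal
# boundary distance for a set of query points against one polygon.
# px, py: query coordinates; poly: n x 2 matrix, implicit closure.
polygonQuery <- function(px, py, poly) {
  n <- nrow(poly)
  jj <- c(2:n, 1L)
  crossings <- integer(length(px))
  dist2 <- rep(Inf, length(px))
  for (i in seq_len(n)) {
    x1 <- poly[i, 1L]; y1 <- poly[i, 2L]
    x2 <- poly[jj[i], 1L]; y2 <- poly[jj[i], 2L]
    # half-open rule: count edges straddling the horizontal ray
    straddle <- (y1 > py) != (y2 > py)
    if (any(straddle)) {
      xi <- x1 + (py - y1) * (x2 - x1) / (y2 - y1)
      crossings <- crossings + as.integer(straddle & px < xi)
    }
    # squared distance to the segment
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
         else 0
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    dist2 <- pmin(dist2, d2)
  }
  list(inside = crossings %% 2L == 1L, dist = sqrt(dist2))
}

#' Tri-state voxel classification from slice contours
#'
#' Assigns the voxel function f(a, b, c) from per-slice contour polygons:
#' a voxel is 0 ("on a contour line") when its in-slice position lies
#' within `onTolerance` of any polygon boundary of its slice; otherwise
#' +1 ("inside") when it falls inside the slice's polygons, and -1
#' ("outside all contour lines") otherwise — including every voxel of a
#' slice that has no polygons. With the default `rule = "evenodd"` a point
#' is inside when it is covered by an odd number of polygons, so nested
#' contours of a hollow organ leave the lumen outside; `rule = "any"`
#' takes "within any contour line" literally and classifies a point as
#' inside when at least one polygon contains it (which fills lumens).
#'
#' @param dims,spacing,origin Target grid geometry (see [voxelGrid()]).
#' @param contours A [ContourSet-class]; slice indices must fall inside
#'   the grid.
#' @param onTolerance Distance in mm within which a voxel counts as on a
#'   contour (default 0: exact hits only).
#' @param rule `"evenodd"` (default) or `"any"`; see above.
#' @return A [TriStateField-class].
#' @export
classifyVoxels <- function(dims, spacing, origin, contours, onTolerance = 0,
                           rule = c("evenodd", "any")) {
  rule <- match.arg(rule)
  if (!is(contours, "ContourSet")) stopf("'contours' must be a ContourSet")
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(dims < 2L))
    stopf("'dims' must be 3 integers, each >= 2")
  if (onTolerance < 0) stopf("'onTolerance' must be >= 0")
  ax <- contours@sliceAxis
  inPlane <- setdiff(1:3, ax)
  labels <- array(-1L, dims)
  nx <- dims[inPlane[1L]]; ny <- dims[inPlane[2L]]
  px <- rep(origin[inPlane[1L]] + (seq_len(nx) - 1) * spacing[inPlane[1L]],
            times = ny)
  py <- rep(origin[inPlane[2L]] + (seq_len(ny) - 1) * spacing[inPlane[2L]],
            each = nx)
  for (sl in contours@slices) {
    k <- sl$index
    if (k < 1L || k > dims[ax])
      stopf("contour slice index %d outside the grid (axis %d has %d slices)",
            k, ax, dims[ax])
    if (length(sl$polygons) == 0L) next
    insideCount <- integer(length(px))
    minDist <- rep(Inf, length(px))
    for (p in sl$polygons) {
      q <- polygonQuery(px, py, p)
      insideCount <- insideCount + as.integer(q$inside)
      minDist <- pmin(minDist, q$dist)
    }
    lab <- rep(-1L, length(px))
    inside <- if (rule == "evenodd") insideCount %% 2L == 1L else insideCount > 0L
    lab[inside] <- 1L
    lab[minDist <= onTolerance] <- 0L
    slab <- matrix(lab, nx, ny)
    switch(ax,
      labels[k, , ] <- slab,
      labels[, k, ] <- slab,
      labels[, , k] <- slab)
  }
  triStateField(labels, spacing, origin)
}

#' Tri-state classification of an implicit-function sample
#'
#' Maps sampled implicit values to the voxel function by sign: values
#' within `zeroTolerance` of zero become 0 ("on the surface"), positive
#' values +1, negative values -1. This is the contour-free route into the
#' reconstruction for data that already carry a signed field.
#'
#' @param grid A [VoxelGrid-class].
#' @param zeroTolerance Non-negative half-width of the "on" band.
#' @return A [TriStateField-class] with the grid's geometry.
#' @examples
#' g <- voxelGrid(array(c(-2, 0, 3, 1, -1, 2, 0, -3), c(2, 2, 2)))
#' fieldLabels(classifyImplicit(g))
#' @export
classifyImplicit <- function(grid, zeroTolerance = 0) {
  if (!is(grid, "VoxelGrid")) stopf("'grid' must be a VoxelGrid")
  if (zeroTolerance < 0) stopf("'zeroTolerance' must be >= 0")
  v <- grid@values
  lab <- array(0L, dim(v))
  lab[v > zeroTolerance] <- 1L
  lab[v < -zeroTolerance] <- -1L
  triStateField(lab, grid@spacing, grid@origin)
}
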