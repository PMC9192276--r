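#' @include casetable.R constructors.R
NULL

# pad a tri-state label array with a one-voxel outside (-1) shell so that
# surfaces close at the volume boundary
padLabels <- function(field) {
  d <- dim(field@labels)
  pd <- d + 2L
  P <- array(-1L, pd)
  P[2:(pd[1L] - 1L), 2:(pd[2L] - 1L), 2:(pd[3L] - 1L)] <- field@labels
  list(P = P, pd = pd, originP = field@origin - field@spacing)
}

#' Extract a triangle surface from a tri-state field
#'
#' Runs a modified marching-cubes pass over the voxel classification
#' f(a, b, c). Cell corners labeled 0 or +1 count as inside for the
#' 256-entry case-table lookup; each sign-crossing cell edge contributes a
#' surface vertex at its exact midpoint, except that a crossing edge whose
#' inside endpoint is labeled 0 places the vertex exactly on that grid
#' point (the surface passes through voxels that lie on a contour line).
#' Shared vertices are welded across cells by exact edge identity, so the
#' output is edge-connected and — when the inside region does not touch
#' the array boundary before padding — watertight. The volume is padded
#' with -1 so surfaces close at the array boundary. Triangles that
#' degenerate when 0-snapping merges their vertices are dropped.
#'
#' @param field A [TriStateField-class].
#' @return A [TriMesh-class] with outward-oriented faces (no normals; see
#'   [vertexNormals()]). A field with a single label yields an empty mesh.
#' @examples
#' lab <- array(-1L, c(3, 3, 3)); lab[2, 2, 2] <- 1L
#' m <- extractSurface(triStateField(lab))
#' meshStats(m)   # an octahedron around the center voxel
#' @export
extractSurface <- function(field) {
  if (!is(field, "TriStateField")) stopf("'field' must be a TriStateField")
  ct <- mcCaseTable()
  geo <- ct$geometry
  pad <- padLabels(field)
  P <- pad$P
  pd <- pad$pd
  ntot <- prod(pd)
  B <- P >= 0L

  # per-cell corner configuration (cells indexed by their lower corner)
  nc <- pd - 1L
  lo <- list(1:(pd[1L] - 1L), 1:(pd[2L] - 1L), 1:(pd[3L] - 1L))
  hi <- list(2:pd[1L], 2:pd[2L], 2:pd[3L])
  cfg <- array(0L, nc)
  for (c in 1:8) {
    off <- geo$offsets[c, ]
    sub <- B[if (off[1L]) hi[[1L]] else lo[[1L]],
             if (off[2L]) hi[[2L]] else lo[[2L]],
             if (off[3L]) hi[[3L]] else lo[[3L]]]
    cfg <- cfg + as.integer(sub) * bitwShiftL(1L, c - 1L)
  }
  act <- which(cfg > 0L & cfg < 255L)
  if (length(act) == 0L) return(triMesh(NULL, NULL))

  cellIdx <- arrayInd(act, nc)
  cfgv <- cfg[act]
  strideP <- c(1, pd[1L], pd[1L] * pd[2L])

  faceKeys <- vector("list", 256L)
  groups <- split(seq_along(act), cfgv)
  for (g in names(groups)) {
    cfgI <- as.integer(g)
    tris <- ct$triangles[[cfgI + 1L]]
    if (nrow(tris) == 0L) next
    rows <- groups[[g]]
    idx <- cellIdx[rows, , drop = FALSE]
    base <- (idx[, 1L] - 1) + (idx[, 2L] - 1) * strideP[2L] +
      (idx[, 3L] - 1) * strideP[3L] + 1
    usedEdges <- sort(unique(as.vector(tris)))
    keyByEdge <- matrix(0, length(rows), 12L)
    for (e in usedEdges) {
      ca <- geo$edges[e, 1L]; cb <- geo$edges[e, 2L]
      ia <- base + sum(geo$offsets[ca, ] * strideP)
      ib <- base + sum(geo$offsets[cb, ] * strideP)
      la <- P[ia]
      plus <- ifelse(la >= 0L, ia, ib)
      snapped <- P[plus] == 0L
      lo_i <- pmin(ia, ib); hi_i <- pmax(ia, ib)
      keyByEdge[, e] <- ifelse(snapped, -plus, (lo_i - 1) * ntot + hi_i)
    }
    fk <- matrix(0, length(rows) * nrow(tris), 3L)
    for (t in seq_len(nrow(tris))) {
      fk[seq_along(rows) + (t - 1L) * length(rows), ] <-
        keyByEdge[, tris[t, ], drop = FALSE]
    }
    faceKeys[[cfgI + 1L]] <- fk
  }
  fk <- do.call(rbind, faceKeys[!vapply(faceKeys, is.null, logical(1))])

  keys <- unique(as.vector(fk))
  faces <- matrix(match(fk, keys), ncol = 3L)
  keep <- faces[, 1L] != faces[, 2L] & faces[, 2L] != faces[, 3L] &
    faces[, 1L] != faces[, 3L]
  faces <- faces[keep, , drop = FALSE]

  # vertex coordinates: snapped keys are -(point index); edge keys encode
  # the two endpoint indices
  snap <- keys < 0
  verts <- matrix(0, length(keys), 3L)
  toWorld <- function(lin) {
    indexToWorld(arrayInd(lin, pd), field@spacing, pad$originP)
  }
  if (any(snap)) verts[snap, ] <- toWorld(-keys[snap])
  if (any(!snap)) {
    k <- keys[!snap]
    i1 <- (k - 1) %/% ntot + 1
    i2 <- (k - 1) %% ntot + 1
    verts[!snap, ] <- (toWorld(i1) + toWorld(i2)) / 2
  }

  # drop vertices orphaned by degenerate-triangle removal
  used <- sort(unique(as.vector(faces)))
  remap <- integer(length(keys))
  remap[used] <- seq_along(used)
  triMesh(verts[used, , drop = FALSE], matrix(remap[faces], ncol = 3L))
}

# central-difference point normals at the given padded-grid linear
# indices; one-sided differences at the padded-volume border
pointNormals <- function(P, pd, lin) {
  idx <- arrayInd(lin, pd)
  strideP <- c(1L, pd[1L], pd[1L] * pd[2L])
  N <- matrix(0, length(lin), 3L)
  for (a in 1:3) {
    atLo <- idx[, a] == 1L
    atHi <- idx[, a] == pd[a]
    im <- lin - ifelse(atLo, 0L, strideP[a])
    ip <- lin + ifelse(atHi, 0L, strideP[a])
    h <- ifelse(atLo | atHi, 1, 2)
    N[, a] <- (P[im] - P[ip]) / h
  }
  N
}

#' Central-difference vertex normals
#'
#' Estimates outward unit normals for a mesh extracted from a tri-state
#' field. At each grid point the normal is the central difference of the
#' voxel function along each axis, e.g. (f(a-1, b, c) - f(a+1, b, c)) / 2
#' along the first axis (one-sided at volume borders); since f is +1
#' inside and -1 outside, this points from the inside toward the outside.
#' A midpoint vertex receives the equal-weight average of its edge's two
#' endpoint normals; a vertex snapped onto a 0-labeled grid point receives
#' that point's normal. Results are normalized to unit length; vertices
#' whose raw difference vanishes fall back to the area-weighted average of
#' their incident face normals.
#'
#' @param field The [TriStateField-class] the mesh was extracted from.
#' @param mesh The [TriMesh-class] returned by [extractSurface()].
#' @return `mesh` with the `normals` slot filled.
#' @export
vertexNormals <- function(field, mesh) {
  if (!is(field, "TriStateField")) stopf("'field' must be a TriStateField")
  if (!is(mesh, "TriMesh")) stopf("'mesh' must be a TriMesh")
  nv <- nrow(mesh@vertices)
  if (nv == 0L) return(mesh)
  pad <- padLabels(field)
  P <- pad$P
  pd <- pad$pd

  # recover each vertex's generating grid points from its coordinates:
  # extraction places vertices at grid points or exact edge midpoints, so
  # fractional indices are multiples of 1/2 with at most one half-axis
  fi <- sweep(sweep(mesh@vertices, 2L, pad$originP, "-"), 2L,
              field@spacing, "/") + 1
  r <- round(fi * 2) / 2
  if (max(abs(fi - r)) > 1e-6 || any(r < 1) || any(r > rep(pd, each = nv)))
    stopf("mesh does not match the field geometry")
  isHalf <- abs(r %% 1 - 0.5) < 1e-9
  nHalf <- rowSums(isHalf)
  if (any(nHalf > 1L)) stopf("mesh does not match the field geometry")

  strideP <- c(1, pd[1L], pd[1L] * pd[2L])
  linOf <- function(ix) 1 + (ix[, 1L] - 1) * strideP[1L] +
    (ix[, 2L] - 1) * strideP[2L] + (ix[, 3L] - 1) * strideP[3L]
  l1 <- linOf(floor(r))
  l2 <- linOf(ceiling(r))
  needed <- unique(c(l1, l2))
  pn <- pointNormals(P, pd, needed)
  N <- (pn[match(l1, needed), , drop = FALSE] +
        pn[match(l2, needed), , drop = FALSE]) / 2

  len <- sqrt(rowSums(N^2))
  zero <- len < 1e-12
  if (any(zero)) {
    fn <- faceNormalsRaw(mesh)          # magnitude = 2 * area, so summing
    acc <- matrix(0, nv, 3L)            # area-weights the average
    for (k in 1:3) {
      for (a in 1:3) {
        s <- rowsum(fn[, a], mesh@faces[, k])
        acc[as.integer(rownames(s)), a] <- acc[as.integer(rownames(s)), a] + s
      }
    }
    accLen <- sqrt(rowSums(acc^2))
    fallback <- zero & accLen > 1e-12
    N[fallback, ] <- acc[fallback, ] / accLen[fallback]
    N[zero & !fallback, ] <- rep(c(1, 0, 0), each = sum(zero & !fallback))
    len[zero] <- 1
  }
  mesh@normals <- N / len
  validObject(mesh)
  mesh
}

# unnormalized face normals (cross products; magnitude = 2 * triangle area)
faceNormalsRaw <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  a <- v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  b <- v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE]
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}
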