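#' @include constructors.R
NULL

# Cell-local geometry for marching cubes.
#
# Corners 1..8 have offsets (dx, dy, dz) in {0,1}^3 with
# id = 1 + dx + 2*dy + 4*dz. Edges 1..12 connect corner pairs differing
# along exactly one axis. Faces are listed with their 4 corners ordered
# counterclockwise as seen from outside the cell.
mcGeometry <- function() {
  offsets <- cbind(
    dx = bitwAnd(0:7, 1L),
    dy = bitwAnd(bitwShiftR(0:7, 1L), 1L),
    dz = bitwAnd(bitwShiftR(0:7, 2L), 1L)
  )
  edges <- NULL
  for (a in 1:7) {
    for (b in (a + 1):8) {
      if (sum(offsets[a, ] != offsets[b, ]) == 1L) edges <- rbind(edges, c(a, b))
    }
  }
  edgeId <- matrix(0L, 8L, 8L)
  for (e in seq_len(nrow(edges))) {
    edgeId[edges[e, 1L], edges[e, 2L]] <- e
    edgeId[edges[e, 2L], edges[e, 1L]] <- e
  }
  # in-plane axes (u, v) with unit(u) x unit(v) = outward normal
  planeAxes <- list(
    `1+` = c(2L, 3L), `1-` = c(3L, 2L),
    `2+` = c(3L, 1L), `2-` = c(1L, 3L),
    `3+` = c(1L, 2L), `3-` = c(2L, 1L)
  )
  corner_of <- function(off) 1L + off[1L] + 2L * off[2L] + 4L * off[3L]
  faces <- list()
  uv <- rbind(c(0L, 0L), c(1L, 0L), c(1L, 1L), c(0L, 1L))
  for (axis in 1:3) {
    for (side in 0:1) {
      key <- paste0(axis, if (side == 1L) "+" else "-")
      ax <- planeAxes[[key]]
      cs <- integer(4L)
      for (k in 1:4) {
        off <- integer(3L)
        off[axis] <- side
        off[ax[1L]] <- uv[k, 1L]
        off[ax[2L]] <- uv[k, 2L]
        cs[k] <- corner_of(off)
      }
      faces[[length(faces) + 1L]] <- cs
    }
  }
  list(offsets = offsets, edges = edges, edgeId = edgeId, faces = faces)
}

# Build the 256-entry triangle table. For each corner configuration the
# isosurface-boundary segments are generated face by face: walking a
# face's corners counterclockwise (seen from outside), each inside->outside
# crossing starts a segment that ends at the next crossing. On ambiguous
# faces (diagonal inside corners) this convention keeps the two outside
# corners separated, and it is intrinsic to the face, so neighbouring
# cells always agree and the mesh is crack-free. Segments chain into closed
# cycles over the cut edges; each cycle is fan-triangulated. Triangles are
# oriented so normals point from the inside (+) region toward the outside.
buildCaseTable <- function() {
  geo <- mcGeometry()
  table <- vector("list", 256L)
  for (cfg in 0:255) {
    inside <- bitwAnd(bitwShiftR(cfg, 0:7), 1L) == 1L
    segNext <- integer(12L)
    for (cs in geo$faces) {
      sgn <- inside[cs]
      if (all(sgn) || !any(sgn)) next
      for (i in 1:4) {
        a <- cs[i]; b <- cs[i %% 4L + 1L]
        if (inside[a] && !inside[b]) {         # exit crossing
          j <- i
          repeat {
            j <- j %% 4L + 1L
            a2 <- cs[j]; b2 <- cs[j %% 4L + 1L]
            if (inside[a2] != inside[b2]) break
          }
          segNext[geo$edgeId[a, b]] <- geo$edgeId[a2, b2]
        }
      }
    }
    cut <- which(segNext > 0L)
    tris <- NULL
    visited <- logical(12L)
    for (e0 in cut) {
      if (visited[e0]) next
      cyc <- e0
      visited[e0] <- TRUE
      e <- segNext[e0]
      while (e != e0) {
        cyc <- c(cyc, e)
        visited[e] <- TRUE
        e <- segNext[e]
      }
      if (length(cyc) < 3L)
        stop("internal error: degenerate cycle in case-table generation")
      for (k in 2:(length(cyc) - 1L)) {
        tris <- rbind(tris, c(cyc[1L], cyc[k], cyc[k + 1L]))
      }
    }
    table[[cfg + 1L]] <- if (is.null(tris)) matrix(integer(0), 0L, 3L) else tris
  }
  # fix global parity from the single-inside-corner case: the triangle's
  # normal must point away from the inside corner
  midpoint <- function(e) colMeans(geo$offsets[geo$edges[e, ], ])
  tri1 <- table[[2L]]                       # cfg = 1, corner 1 inside
  p <- t(vapply(tri1[1L, ], midpoint, numeric(3L)))
  nrm <- crossprod3(p[2L, ] - p[1L, ], p[3L, ] - p[1L, ])
  outwardness <- sum(nrm * (colMeans(p) - geo$offsets[1L, ]))
  if (outwardness < 0) {
    table <- lapply(table, function(m) m[, c(1L, 3L, 2L), drop = FALSE])
  }
  list(geometry = geo, triangles = table)
}

crossprod3 <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.ctsurfCache <- new.env(parent = emptyenv())

mcCaseTable <- function() {
  if (is.null(.ctsurfCache$casetable)) {
    .ctsurfCache$casetable <- buildCaseTable()
  }
  .ctsurfCache$casetable
}
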