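#' @include constructors.R meshkit.R
NULL

# unit normal of one triangle, or NULL for a degenerate one
triNormal <- function(V, tri) {
  a <- V[tri[2L], ] - V[tri[1L], ]
  b <- V[tri[3L], ] - V[tri[1L], ]
  n <- crossprod3(a, b)
  len <- sqrt(sum(n^2))
  if (len < 1e-300) return(NULL)
  n / len
}

# isoperimetric triangle quality 12*sqrt(3)*area / perimeter^2, the
# area-to-perimeter ratio normalized so an equilateral triangle scores 1
# (the isoperimetric maximum) and a degenerate one 0
triQuality <- function(V, tri) {
  a <- V[tri[2L], ] - V[tri[1L], ]
  b <- V[tri[3L], ] - V[tri[1L], ]
  c <- V[tri[3L], ] - V[tri[2L], ]
  p <- sqrt(sum(a^2)) + sqrt(sum(b^2)) + sqrt(sum(c^2))
  if (p <= 0) return(0)
  area <- sqrt(sum(crossprod3(a, b)^2)) / 2
  12 * sqrt(3) * area / p^2
}

# faces incident to a vertex / to an edge, from a face matrix
facesOfVertex <- function(faces, v) {
  which(faces[, 1L] == v | faces[, 2L] == v | faces[, 3L] == v)
}

# flatness, shape and length terms for an edge, given vertex matrix and
# the incident-face index sets
edgeTermsImpl <- function(V, faces, u, v, triU, triV) {
  triEdge <- intersect(triU, triV)
  both <- union(triU, triV)
  # T: worst normal disagreement among all triangles touching either endpoint
  N <- NULL
  for (t in both) {
    n <- triNormal(V, faces[t, ])
    if (!is.null(n)) N <- rbind(N, n)
  }
  Tval <- if (is.null(N) || nrow(N) < 2L) 0 else {
    dots <- N %*% t(N)
    max(1 - dots[upper.tri(dots)])
  }
  # X: 1 - worst-case-free min quality over the triangles with side s
  Xval <- if (length(triEdge) == 0L) 0 else {
    1 - min(vapply(triEdge, function(t) triQuality(V, faces[t, ]), numeric(1)))
  }
  Gval <- sqrt(sum((V[u, ] - V[v, ])^2))
  list(T = min(max(Tval, 0), 2), X = min(max(Xval, 0), 1), G = Gval)
}

checkEdgeArg <- function(mesh, edge) {
  edge <- as.integer(edge)
  if (length(edge) != 2L || any(edge < 1L) || any(edge > nrow(mesh@vertices)) ||
      edge[1L] == edge[2L])
    stopf("'edge' must be two distinct vertex indices of the mesh")
  sort(edge)
}

#' Flatness term of the collapse priority
#'
#' T(s) = max over pairs of unit normals of the triangles touching either
#' endpoint of the edge s of (1 - dot product). 0 for a perfectly flat
#' neighborhood, 1 at 90 degrees, 2 for a fold-back. Degenerate (zero
#' area) triangles carry no normal and are excluded.
#'
#' @param mesh A [TriMesh-class].
#' @param edge Integer pair of vertex indices.
#' @return Scalar in `[0, 2]`.
#' @export
edgeFlatness <- function(mesh, edge) {
  edge <- checkEdgeArg(mesh, edge)
  triU <- facesOfVertex(mesh@faces, edge[1L])
  triV <- facesOfVertex(mesh@faces, edge[2L])
  if (length(union(triU, triV)) == 0L)
    stopf("edge (%d, %d) has no incident triangle", edge[1L], edge[2L])
  edgeTermsImpl(mesh@vertices, mesh@faces, edge[1L], edge[2L], triU, triV)$T
}

#' Shape-coefficient term of the collapse priority
#'
#' For every triangle having the edge s as a side, the isoperimetric
#' quality q = 12*sqrt(3)*area / perimeter^2 is 1 for an equilateral
#' triangle and tends to 0 as the triangle degenerates; X(s) = 1 - min q,
#' so edges bordered by ill-shaped triangles get a higher X and are
#' removed earlier.
#'
#' @inheritParams edgeFlatness
#' @return Scalar in `[0, 1]`.
#' @export
shapeCoefficient <- function(mesh, edge) {
  edge <- checkEdgeArg(mesh, edge)
  triU <- facesOfVertex(mesh@faces, edge[1L])
  triV <- facesOfVertex(mesh@faces, edge[2L])
  triEdge <- intersect(triU, triV)
  if (length(triEdge) == 0L)
    stopf("edge (%d, %d) has no incident triangle", edge[1L], edge[2L])
  edgeTermsImpl(mesh@vertices, mesh@faces, edge[1L], edge[2L], triU, triV)$X
}

#' Collapse priority of one edge
#'
#' Evaluates Y(s) = Ct*T(s) + Cx*X(s) + Cg*G(s) for one edge, where T is
#' the flatness term ([edgeFlatness()]), X the shape coefficient
#' ([shapeCoefficient()]) and G the edge length divided by the config's
#' `lengthScale` (mean input edge length when unset). Low Y marks short,
#' flat, well-shaped edges whose collapse loses least geometry.
#'
#' @inheritParams edgeFlatness
#' @param config A [SimplifyConfig-class].
#' @return An [EdgeRecord-class].
#' @export
edgePriority <- function(mesh, edge, config = simplifyConfig(targetRatio = 1)) {
  edge <- checkEdgeArg(mesh, edge)
  triU <- facesOfVertex(mesh@faces, edge[1L])
  triV <- facesOfVertex(mesh@faces, edge[2L])
  if (length(union(triU, triV)) == 0L)
    stopf("edge (%d, %d) has no incident triangle", edge[1L], edge[2L])
  terms <- edgeTermsImpl(mesh@vertices, mesh@faces, edge[1L], edge[2L],
                         triU, triV)
  ls <- if (is.na(config@lengthScale)) meanEdgeLength(mesh) else config@lengthScale
  G <- terms$G / ls
  new("EdgeRecord", edge = edge, T = terms$T, X = terms$X, G = G,
      Y = config@ct * terms$T + config@cx * terms$X + config@cg * G)
}

meanEdgeLength <- function(mesh) {
  ed <- meshEdges(mesh@faces)$edges
  if (nrow(ed) == 0L) return(1)
  mean(sqrt(rowSums((mesh@vertices[ed[, 1L], , drop = FALSE] -
                     mesh@vertices[ed[, 2L], , drop = FALSE])^2)))
}

#' Simplify a mesh by priority-driven edge collapse
#'
#' Repeatedly collapses the edge with the smallest priority
#' Y(s) = Ct*T(s) + Cx*X(s) + Cg*G(s) (ties broken by the smallest vertex
#' index pair), merging its endpoints at the edge midpoint, until the face
#' count reaches the configured target or no edge can be collapsed.
#' A candidate collapse is skipped — and retried only after a neighboring
#' collapse changes its surroundings — when it is not an interior manifold
#' edge, when it violates the link condition (which would pinch the
#' surface), or when it would flip a surviving face normal by more than 90
#' degrees or squash a face to zero area. Priorities of edges in the
#' modified neighborhood are recomputed after every collapse, so the
#' selection is always globally greedy on current priorities. A watertight
#' input therefore stays watertight and keeps its Euler characteristic.
#'
#' @param mesh An edge-manifold [TriMesh-class] (every edge bordering at
#'   most two faces; boundary edges are left uncollapsed).
#' @param config A [SimplifyConfig-class]; its target must be >= 4 faces.
#' @param trace Logical; when `TRUE` the result carries an attribute
#'   `"collapses"`, a data frame of the collapsed edges (surviving vertex
#'   `u`, removed vertex `v`, priority `Y`) in execution order, with
#'   vertex indices of the input mesh.
#' @return A simplified [TriMesh-class] (normals are dropped).
#' @examples
#' lab <- array(-1L, c(3, 3, 3)); lab[2, 2, 2] <- 1L
#' oct <- extractSurface(triStateField(lab))
#' decimateMesh(oct, simplifyConfig(targetFaces = 8))   # already at target
#' @export
decimateMesh <- function(mesh, config, trace = FALSE) {
  if (!is(mesh, "TriMesh")) stopf("'mesh' must be a TriMesh")
  if (!is(config, "SimplifyConfig")) stopf("'config' must be a SimplifyConfig")
  nfIn <- nrow(mesh@faces)
  target <- if (!is.na(config@targetFaces)) config@targetFaces else
    max(4L, as.integer(floor(config@targetRatio * nfIn)))
  if (target < 4L) stopf("face target %d is below the minimal closed mesh (4)", target)
  ed <- meshEdges(mesh@faces)
  if (any(ed$count > 2L))
    stopf("mesh is not edge-manifold: an edge borders %d faces", max(ed$count))
  if (nfIn <= target) {
    out <- triMesh(mesh@vertices, mesh@faces)
    if (trace) attr(out, "collapses") <-
      data.frame(u = integer(0), v = integer(0), Y = numeric(0))
    return(out)
  }

  V <- mesh@vertices
  F <- mesh@faces
  nv <- nrow(V)
  fAlive <- rep(TRUE, nfIn)
  nAlive <- nfIn
  vertFaces <- vector("list", nv)
  for (k in 1:3) {
    sp <- split(seq_len(nfIn), F[, k])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      vertFaces[[i]] <- c(vertFaces[[i]], sp[[nm]])
    }
  }
  lengthScale <- if (is.na(config@lengthScale)) {
    mean(sqrt(rowSums((V[ed$edges[, 1L], , drop = FALSE] -
                       V[ed$edges[, 2L], , drop = FALSE])^2)))
  } else config@lengthScale

  # edge registry (a < b); lazily grown when collapses create new links
  nE <- nrow(ed$edges)
  eA <- ed$edges[, 1L]; eB <- ed$edges[, 2L]
  eAlive <- rep(TRUE, nE)
  eBlocked <- rep(FALSE, nE)
  eY <- numeric(nE)
  keyEnv <- new.env(parent = emptyenv(), size = 4L * nE)
  for (i in seq_len(nE)) assign(paste(eA[i], eB[i]), i, envir = keyEnv)
  vertEdges <- vector("list", nv)
  for (i in seq_len(nE)) {
    vertEdges[[eA[i]]] <- c(vertEdges[[eA[i]]], i)
    vertEdges[[eB[i]]] <- c(vertEdges[[eB[i]]], i)
  }

  computeY <- function(i) {
    u <- eA[i]; v <- eB[i]
    terms <- edgeTermsImpl(V, F, u, v,
                           vertFaces[[u]][fAlive[vertFaces[[u]]]],
                           vertFaces[[v]][fAlive[vertFaces[[v]]]])
    config@ct * terms$T + config@cx * terms$X + config@cg * terms$G / lengthScale
  }
  for (i in seq_len(nE)) eY[i] <- computeY(i)

  neighborsOf <- function(u) {
    fs <- vertFaces[[u]][fAlive[vertFaces[[u]]]]
    setdiff(unique(as.vector(F[fs, , drop = FALSE])), u)
  }

  collapses <- list()
  repeat {
    if (nAlive <= target) break
    cand <- which(eAlive & !eBlocked)
    if (length(cand) == 0L) break
    ymin <- min(eY[cand])
    tied <- cand[eY[cand] == ymin]
    if (length(tied) > 1L) tied <- tied[order(eA[tied], eB[tied])]
    i <- tied[1L]
    u <- eA[i]; v <- eB[i]

    triU <- vertFaces[[u]][fAlive[vertFaces[[u]]]]
    triV <- vertFaces[[v]][fAlive[vertFaces[[v]]]]
    shared <- intersect(triU, triV)
    ok <- length(shared) == 2L
    if (ok) {
      # link condition: the endpoints' common neighbors must be exactly
      # the two vertices opposite the shared faces
      Nu <- setdiff(unique(as.vector(F[triU, , drop = FALSE])), u)
      Nv <- setdiff(unique(as.vector(F[triV, , drop = FALSE])), v)
      opp <- setdiff(unique(as.vector(F[shared, , drop = FALSE])), c(u, v))
      common <- intersect(Nu, Nv)
      ok <- length(opp) == 2L && setequal(common, opp)
    }
    if (ok) {
      # orientation guard on the surviving faces
      newPos <- (V[u, ] + V[v, ]) / 2
      for (t in setdiff(union(triU, triV), shared)) {
        tri <- F[t, ]
        before <- triNormal(V, tri)
        Vt <- V
        Vt[u, ] <- newPos; Vt[v, ] <- newPos
        after <- triNormal(Vt, tri)
        if (is.null(before) || is.null(after) || sum(before * after) <= 0) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) {
      eBlocked[i] <- TRUE
      next
    }

    # ---- perform the collapse (u survives at the midpoint) ----
    V[u, ] <- (V[u, ] + V[v, ]) / 2
    fAlive[shared] <- FALSE
    nAlive <- nAlive - length(shared)
    for (t in setdiff(triV, shared)) {
      F[t, F[t, ] == v] <- u
      vertFaces[[u]] <- c(vertFaces[[u]], t)
    }
    vertFaces[[v]] <- integer(0)
    # retire edges at v; re-key the surviving links onto u
    for (j in vertEdges[[v]]) {
      if (!eAlive[j]) next
      w <- if (eA[j] == v) eB[j] else eA[j]
      eAlive[j] <- FALSE
      if (w == u) next
      a <- min(u, w); b <- max(u, w)
      ex <- get0(paste(a, b), envir = keyEnv, ifnotfound = NULL)
      if (is.null(ex) || !eAlive[ex]) {
        nE <- nE + 1L
        eA[nE] <- a; eB[nE] <- b
        eAlive[nE] <- TRUE; eBlocked[nE] <- FALSE; eY[nE] <- 0
        assign(paste(a, b), nE, envir = keyEnv)
        vertEdges[[a]] <- c(vertEdges[[a]], nE)
        vertEdges[[b]] <- c(vertEdges[[b]], nE)
      }
    }
    vertEdges[[v]] <- integer(0)
    vertFaces[[u]] <- unique(vertFaces[[u]][fAlive[vertFaces[[u]]]])
    vertEdges[[u]] <- unique(vertEdges[[u]][eAlive[vertEdges[[u]]]])
    # refresh priorities across the modified neighborhood
    region <- c(u, neighborsOf(u))
    touched <- unique(unlist(vertEdges[region]))
    touched <- touched[eAlive[touched]]
    for (j in touched) {
      eY[j] <- computeY(j)
      eBlocked[j] <- FALSE
    }
    if (trace) collapses[[length(collapses) + 1L]] <- c(u, v, ymin)
  }

  keepF <- which(fAlive)
  usedV <- sort(unique(as.vector(F[keepF, , drop = FALSE])))
  remap <- integer(nv)
  remap[usedV] <- seq_along(usedV)
  out <- triMesh(V[usedV, , drop = FALSE],
                 matrix(remap[F[keepF, , drop = FALSE]], ncol = 3L))
  if (trace) {
    tr <- if (length(collapses)) do.call(rbind, collapses) else
      matrix(numeric(0), 0L, 3L)
    attr(out, "collapses") <- data.frame(u = as.integer(tr[, 1L]),
                                         v = as.integer(tr[, 2L]),
                                         Y = tr[, 3L])
  }
  out
}
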