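# Shared fixtures and independent oracles for the test suite. Everything
# here is deliberately written from first principles (no calls into the
# code paths under test) so the tests compare two independent routes.

# regular octahedron with apexes at +/- h on each axis, outward winding
octahedronMesh <- function(h = 0.5) {
  triMesh(
    rbind(c(h, 0, 0), c(-h, 0, 0), c(0, h, 0), c(0, -h, 0),
          c(0, 0, h), c(0, 0, -h)),
    rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
          c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  )
}

# signed polygon area by the shoelace formula
shoelace <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

# sphere phantom sampled on an n^3 grid spanning [-extent/2, extent/2]
sphereField <- function(radius = 12, n = 64, extent = 32) {
  sp <- rep(extent / (n - 1), 3)
  orig <- -(n - 1) * sp / 2
  g <- voxelize(makeSpherePhantom(radius), rep(n, 3), sp, orig)
  classifyImplicit(g)
}

# random union-of-spheres blob label field. Pairs of spheres are kept
# either clearly separated or clearly overlapping (by >= 2 voxels), so the
# discrete topology of the union is well resolved at the grid scale and
# any correct iso-surfacer must agree on it.
randomBlobField <- function(n = 32, seed = 1) {
  set.seed(seed)
  k <- sample(3:6, 1)
  ctr <- matrix(NA_real_, k, 3)
  r <- numeric(k)
  placed <- 0
  while (placed < k) {
    c0 <- runif(3, 10, n - 9)
    r0 <- runif(1, 3.5, 6.5)
    ok <- TRUE
    if (placed > 0) for (i in 1:placed) {
      d <- sqrt(sum((ctr[i, ] - c0)^2))
      if ((d > r[i] + r0 - 2 && d < r[i] + r0 + 2) ||
          d < abs(r[i] - r0) + 2) { ok <- FALSE; break }
    }
    if (ok) { placed <- placed + 1; ctr[placed, ] <- c0; r[placed] <- r0 }
  }
  x <- seq_len(n)
  co <- cbind(rep(x, n * n), rep(rep(x, each = n), n), rep(x, each = n * n))
  f <- rep(-Inf, n^3)
  for (i in 1:k) f <- pmax(f, r[i] - sqrt(rowSums(sweep(co, 2, ctr[i, ])^2)))
  lab <- array(ifelse(f > 0, 1L, -1L), rep(n, 3))
  lab[c(1, n), , ] <- -1L; lab[, c(1, n), ] <- -1L; lab[, , c(1, n)] <- -1L
  lab
}

# reference marching cubes via scikit-image (independent implementation);
# returns euler characteristic, |volume| and watertightness
refMarchingCubes <- function(lab) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(c(paste(dim(lab), collapse = " "),
               paste(as.vector(lab), collapse = " ")), tf)
  out <- system2("python", c(shQuote(test_path("ref_mc.py")), shQuote(tf)),
                 stdout = TRUE)
  p <- strsplit(out[length(out)], " ")[[1]]
  list(chi = as.integer(p[1]), volume = as.numeric(p[2]),
       watertight = identical(p[3], "True"))
}

# tie-aware Mann-Whitney concordance probability by brute force over all
# positive-negative score pairs
aucByConcordance <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# 6-connected components of a logical 3D array (breadth-first flood fill)
countComponents <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  strides <- c(1L, d[1L], d[1L] * d[2L])
  idx <- which(mask)
  comp <- 0L
  for (s in idx) {
    if (lab[s] > 0L) next
    comp <- comp + 1L
    queue <- s
    lab[s] <- comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, d)
      for (a in 1:3) {
        for (dd in c(-1L, 1L)) {
          if (ci[a] + dd < 1L || ci[a] + dd > d[a]) next
          nb <- cur + dd * strides[a]
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- comp
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  comp
}

# --- independent greedy-decimation oracle -------------------------------
# Recomputes every edge's priority from scratch at every step and applies
# the first valid collapse in (Y, vmin, vmax) order: the brute-force
# counterpart of the incremental queue inside decimateMesh().

oracleEdgeY <- function(V, F, u, v, ct, cx, cg, lengthScale) {
  inU <- F[, 1] == u | F[, 2] == u | F[, 3] == u
  inV <- F[, 1] == v | F[, 2] == v | F[, 3] == v
  both <- which(inU | inV)
  N <- NULL
  for (t in both) {
    a <- V[F[t, 2], ] - V[F[t, 1], ]
    b <- V[F[t, 3], ] - V[F[t, 1], ]
    n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
    len <- sqrt(sum(n^2))
    if (len > 1e-300) N <- rbind(N, n / len)
  }
  Tv <- if (is.null(N) || nrow(N) < 2) 0 else {
    dots <- N %*% t(N)
    max(1 - dots[upper.tri(dots)])
  }
  side <- which(inU & inV)
  Xv <- if (length(side) == 0) 0 else {
    1 - min(vapply(side, function(t) {
      a <- V[F[t, 2], ] - V[F[t, 1], ]
      b <- V[F[t, 3], ] - V[F[t, 1], ]
      cc <- V[F[t, 3], ] - V[F[t, 2], ]
      p <- sqrt(sum(a^2)) + sqrt(sum(b^2)) + sqrt(sum(cc^2))
      if (p <= 0) return(0)
      n <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
             a[1] * b[2] - a[2] * b[1])
      12 * sqrt(3) * (sqrt(sum(n^2)) / 2) / p^2
    }, numeric(1)))
  }
  Gv <- sqrt(sum((V[u, ] - V[v, ])^2)) / lengthScale
  ct * Tv + cx * Xv + cg * Gv
}

oracleCollapseValid <- function(V, F, u, v) {
  inU <- F[, 1] == u | F[, 2] == u | F[, 3] == u
  inV <- F[, 1] == v | F[, 2] == v | F[, 3] == v
  shared <- which(inU & inV)
  if (length(shared) != 2) return(FALSE)
  Nu <- setdiff(unique(as.vector(F[inU, , drop = FALSE])), u)
  Nv <- setdiff(unique(as.vector(F[inV, , drop = FALSE])), v)
  opp <- setdiff(unique(as.vector(F[shared, , drop = FALSE])), c(u, v))
  if (length(opp) != 2 || !setequal(intersect(Nu, Nv), opp)) return(FALSE)
  newPos <- (V[u, ] + V[v, ]) / 2
  for (t in setdiff(which(inU | inV), shared)) {
    tri <- F[t, ]
    P <- V[tri, , drop = FALSE]
    n0 <- c((P[2, 2] - P[1, 2]) * (P[3, 3] - P[1, 3]) -
              (P[2, 3] - P[1, 3]) * (P[3, 2] - P[1, 2]),
            (P[2, 3] - P[1, 3]) * (P[3, 1] - P[1, 1]) -
              (P[2, 1] - P[1, 1]) * (P[3, 3] - P[1, 3]),
            (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
              (P[2, 2] - P[1, 2]) * (P[3, 1] - P[1, 1]))
    P2 <- P
    for (k in which(tri == u | tri == v)) P2[k, ] <- newPos
    n1 <- c((P2[2, 2] - P2[1, 2]) * (P2[3, 3] - P2[1, 3]) -
              (P2[2, 3] - P2[1, 3]) * (P2[3, 2] - P2[1, 2]),
            (P2[2, 3] - P2[1, 3]) * (P2[3, 1] - P2[1, 1]) -
              (P2[2, 1] - P2[1, 1]) * (P2[3, 3] - P2[1, 3]),
            (P2[2, 1] - P2[1, 1]) * (P2[3, 2] - P2[1, 2]) -
              (P2[2, 2] - P2[1, 2]) * (P2[3, 1] - P2[1, 1]))
    if (sqrt(sum(n0^2)) < 1e-300 || sqrt(sum(n1^2)) < 1e-300 ||
        sum(n0 * n1) <= 0) return(FALSE)
  }
  TRUE
}

# Replays a decimateMesh() collapse trace step by step, checking each
# recorded collapse against a fresh brute-force recomputation of every
# current edge: the collapsed edge must be valid, its recorded priority
# must match the oracle's arithmetic, and no other valid edge may have a
# strictly smaller priority (with the (Y, vmin, vmax) tie order).
# Returns the number of verified steps.
oracleVerifyGreedy <- function(mesh, tr, ct = 1, cx = 1, cg = 1) {
  V <- meshVertices(mesh)
  F <- meshFaces(mesh)
  e0 <- unique(rbind(cbind(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2])),
                     cbind(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3])),
                     cbind(pmin(F[, 1], F[, 3]), pmax(F[, 1], F[, 3]))))
  lengthScale <- mean(sqrt(rowSums((V[e0[, 1], , drop = FALSE] -
                                    V[e0[, 2], , drop = FALSE])^2)))
  for (step in seq_len(nrow(tr))) {
    u <- tr$u[step]; v <- tr$v[step]
    stopifnot(u < v)
    if (!oracleCollapseValid(V, F, u, v)) {
      stop(sprintf("step %d: collapse (%d, %d) is not valid", step, u, v))
    }
    yChosen <- oracleEdgeY(V, F, u, v, ct, cx, cg, lengthScale)
    if (abs(yChosen - tr$Y[step]) > 1e-9) {
      stop(sprintf("step %d: recorded Y %.12g != oracle Y %.12g", step,
                   tr$Y[step], yChosen))
    }
    ed <- unique(rbind(cbind(pmin(F[, 1], F[, 2]), pmax(F[, 1], F[, 2])),
                       cbind(pmin(F[, 2], F[, 3]), pmax(F[, 2], F[, 3])),
                       cbind(pmin(F[, 1], F[, 3]), pmax(F[, 1], F[, 3]))))
    for (i in seq_len(nrow(ed))) {
      a <- ed[i, 1]; b <- ed[i, 2]
      if (a == u && b == v) next
      yOther <- oracleEdgeY(V, F, a, b, ct, cx, cg, lengthScale)
      if (yOther < yChosen - 1e-9 && oracleCollapseValid(V, F, a, b)) {
        stop(sprintf(
          "step %d: valid edge (%d, %d) with Y %.12g beats chosen (%d, %d) with Y %.12g",
          step, a, b, yOther, u, v, yChosen))
      }
    }
    V[u, ] <- (V[u, ] + V[v, ]) / 2
    inU <- F[, 1] == u | F[, 2] == u | F[, 3] == u
    inV <- F[, 1] == v | F[, 2] == v | F[, 3] == v
    F <- F[!(inU & inV), , drop = FALSE]
    F[F == v] <- u
  }
  nrow(tr)
}
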