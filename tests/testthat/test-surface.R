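test_that("a single inside voxel reconstructs as a midpoint octahedron", {
  lab <- array(-1L, c(3, 3, 3))
  lab[2, 2, 2] <- 1L
  m <- extractSurface(triStateField(lab))
  st <- meshStats(m)
  expect_identical(st$nVertices, 6L)
  expect_identical(st$nEdges, 12L)
  expect_identical(st$nFaces, 8L)
  expect_identical(st$eulerCharacteristic, 2L)
  expect_true(st$watertight)
  # all six vertices at the midpoints of the center voxel's grid edges
  expected <- rbind(c(1.5, 1, 1), c(0.5, 1, 1), c(1, 1.5, 1),
                    c(1, 0.5, 1), c(1, 1, 1.5), c(1, 1, 0.5))
  v <- meshVertices(m)
  expect_equal(v[order(v[, 1], v[, 2], v[, 3]), ],
               expected[order(expected[, 1], expected[, 2], expected[, 3]), ])
  expect_gt(st$enclosedVolume, 0)   # outward orientation
})

test_that("uniform fields yield an empty mesh", {
  empty <- extractSurface(triStateField(array(-1L, c(4, 4, 4))))
  expect_identical(nrow(meshFaces(empty)), 0L)
  # an all-inside field is closed off by the -1 padding instead
  full <- extractSurface(triStateField(array(1L, c(4, 4, 4))))
  expect_true(meshStats(full)$watertight)
})

test_that("every vertex sits on a grid point or an exact edge midpoint", {
  lab <- randomBlobField(24, seed = 42)
  lab[12, 12, 12] <- 0L   # force some zero-state snapping too
  f <- triStateField(lab, spacing = c(0.8, 1.1, 1.3), origin = c(-1, 2, 0.5))
  v <- meshVertices(extractSurface(f))
  fi <- sweep(sweep(v, 2, gridOrigin(f) - gridSpacing(f), "-"), 2,
              gridSpacing(f), "/")
  expect_lt(max(abs(fi * 2 - round(fi * 2))), 1e-9)
})

test_that("zero-state corners snap crossing vertices onto the grid point", {
  lab <- array(-1L, c(3, 3, 3))
  lab[2, 2, 2] <- 0L    # on-contour voxel surrounded by outside
  m <- extractSurface(triStateField(lab))
  # every crossing edge ends at the 0 vertex: the surface collapses there
  # and all triangles degenerate away
  expect_identical(nrow(meshFaces(m)), 0L)

  lab2 <- array(-1L, c(4, 3, 3))
  lab2[2, 2, 2] <- 1L
  lab2[3, 2, 2] <- 0L   # inside voxel with an on-contour neighbor
  m2 <- extractSurface(triStateField(lab2))
  st2 <- meshStats(m2)
  expect_true(st2$watertight)
  # the grid point (3, 2, 2) -> world (2, 1, 1) is itself a mesh vertex
  hit <- apply(meshVertices(m2), 1, function(p) all(abs(p - c(2, 1, 1)) < 1e-12))
  expect_true(any(hit))
})

test_that("surfaces of interior blobs are watertight with chi = 2 per ball", {
  for (seed in c(3, 11)) {
    lab <- randomBlobField(28, seed)
    st <- meshStats(extractSurface(triStateField(lab)))
    expect_true(st$watertight)
    expect_identical(st$eulerCharacteristic %% 2L, 0L)
    expect_gt(st$enclosedVolume, 0)
  }
})

test_that("sphere reconstruction volume converges with resolution", {
  ph <- makeSpherePhantom(12)
  err <- vapply(c(32, 48), function(n) {
    st <- meshStats(extractSurface(sphereField(12, n, 32)))
    expect_true(st$watertight)
    expect_identical(st$eulerCharacteristic, 2L)
    abs(st$enclosedVolume - ph@analyticVolume) / ph@analyticVolume
  }, numeric(1))
  expect_lt(err[1], 0.05)
  expect_lte(err[2], err[1])
})

test_that("normals follow the central-difference rule on a half-space", {
  # inside for a <= 5, outside beyond: the interface is the plane a = 5.5
  lab <- array(-1L, c(10, 6, 6))
  lab[1:5, , ] <- 1L
  f <- triStateField(lab)
  m <- vertexNormals(f, extractSurface(f))
  v <- meshVertices(m)
  nr <- meshNormals(m)
  onPlane <- abs(v[, 1] - 4.5) < 1e-9 &
    v[, 2] > 1.1 & v[, 2] < 2.9 & v[, 3] > 1.1 & v[, 3] < 2.9
  expect_gt(sum(onPlane), 0)
  # (f(a-1) - f(a+1)) / 2 = (1 - (-1)) / 2 = +1 along a, 0 elsewhere
  expect_equal(nr[onPlane, , drop = FALSE],
               matrix(rep(c(1, 0, 0), each = sum(onPlane)), ncol = 3))
})

test_that("sphere normals agree with the outward radial direction", {
  f <- sphereField(12, 48, 32)
  m <- vertexNormals(f, extractSurface(f))
  v <- meshVertices(m)
  nr <- meshNormals(m)
  expect_equal(sqrt(rowSums(nr^2)), rep(1, nrow(nr)), tolerance = 1e-9)
  rad <- v / sqrt(rowSums(v^2))
  dp <- rowSums(nr * rad)
  expect_gt(mean(dp > 0), 0.99)
  ang <- acos(pmin(pmax(dp, -1), 1)) * 180 / pi
  expect_lte(median(ang), 30)
})

test_that("normals on a foreign mesh are rejected", {
  f <- sphereField(6, 16, 16)
  other <- octahedronMesh(0.37)   # vertices off the half-grid lattice
  expect_error(vertexNormals(f, other), "match the field")
})
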