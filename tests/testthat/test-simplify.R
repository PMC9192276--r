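# small closed meshes for priority-term checks
flatFan <- function() {
  # two coplanar triangles sharing edge (1, 2)
  triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, -1, 0)),
          rbind(c(1, 2, 3), c(2, 1, 4)))
}

test_that("edge flatness reflects the worst normal disagreement", {
  expect_equal(edgeFlatness(flatFan(), c(1, 2)), 0)
  # perpendicular roof: normals at 90 degrees
  roof <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 0, 1)),
                  rbind(c(1, 2, 3), c(2, 1, 4)))
  expect_equal(edgeFlatness(roof, c(1, 2)), 1)
  # fold-back: opposite normals
  fold <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(0.5, 1, 1e-9)),
                  rbind(c(1, 2, 3), c(2, 1, 4)))
  expect_equal(edgeFlatness(fold, c(1, 2)), 2, tolerance = 1e-6)
  expect_error(edgeFlatness(flatFan(), c(1, 5)), "vertex indices")
})

test_that("shape coefficient is 0 for equilateral and 1 for degenerate", {
  s3 <- sqrt(3) / 2
  equi <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, s3, 0), c(0.5, -s3, 0)),
                  rbind(c(1, 2, 3), c(2, 1, 4)))
  expect_equal(shapeCoefficient(equi, c(1, 2)), 0, tolerance = 1e-12)
  # right isoceles with legs 1: area 1/2, perimeter 2 + sqrt(2), so
  # q = 6 sqrt(3) / (2 + sqrt(2))^2
  iso <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                 matrix(c(1, 2, 3), 1))
  q <- 6 * sqrt(3) / (2 + sqrt(2))^2
  expect_equal(shapeCoefficient(iso, c(1, 2)), 1 - q)
  degen <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                   matrix(c(1, 2, 3), 1))
  expect_equal(shapeCoefficient(degen, c(1, 2)), 1)
})

test_that("edge priority combines the three weighted terms", {
  oct <- octahedronMesh(1)
  cfg <- simplifyConfig(ct = 1, cx = 1, cg = 1, targetRatio = 1,
                        lengthScale = 1)
  rec <- edgePriority(oct, c(1, 3), cfg)
  expect_equal(rec@Y, cfg@ct * rec@T + cfg@cx * rec@X + cfg@cg * rec@G)
  expect_equal(rec@G, sqrt(2))
  # single-term configs isolate each component
  cg <- edgePriority(oct, c(1, 3), simplifyConfig(0, 0, 1, targetRatio = 1,
                                                  lengthScale = 1))
  expect_equal(cg@Y, sqrt(2))
  flat <- edgePriority(flatFan(), c(1, 2),
                       simplifyConfig(2, 0, 0, targetRatio = 1))
  expect_equal(flat@Y, 0)
})

test_that("priority is invariant under rigid motion", {
  f <- sphereField(5, 14, 14)
  m <- extractSurface(f)
  cfg <- simplifyConfig(targetRatio = 1, lengthScale = 1)
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  m2 <- triMesh(meshVertices(m) %*% t(R) + matrix(c(3, -2, 7),
                                                  nrow(meshVertices(m)), 3,
                                                  byrow = TRUE),
                meshFaces(m))
  ed <- meshFaces(m)[1:10, 1:2]
  for (i in seq_len(nrow(ed))) {
    r1 <- edgePriority(m, ed[i, ], cfg)
    r2 <- edgePriority(m2, ed[i, ], cfg)
    expect_equal(r2@T, r1@T, tolerance = 1e-9)
    expect_equal(r2@X, r1@X, tolerance = 1e-9)
    expect_equal(r2@G, r1@G, tolerance = 1e-9)
  }
})

test_that("meeting the target returns the mesh unchanged", {
  oct <- octahedronMesh()
  out <- decimateMesh(oct, simplifyConfig(targetFaces = 8))
  expect_identical(meshFaces(out), meshFaces(oct))
  expect_equal(meshVertices(out), meshVertices(oct))
})

test_that("invalid targets and non-manifold input are rejected", {
  oct <- octahedronMesh()
  expect_error(simplifyConfig(targetFaces = 2), ">= 4")
  expect_error(decimateMesh(oct, simplifyConfig(targetRatio = 0.5,
                                                targetFaces = 6)),
               "exactly one")
  bad <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                       c(0, 0, -1)),
                 rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5)))
  expect_error(decimateMesh(bad, simplifyConfig(targetFaces = 4)),
               "edge-manifold")
})

test_that("every collapse is globally minimal-priority among valid edges", {
  m <- extractSurface(sphereField(3, 9, 12))
  expect_lte(nrow(meshFaces(m)), 200L)
  got <- decimateMesh(m, simplifyConfig(targetFaces = 40L), trace = TRUE)
  tr <- attr(got, "collapses")
  expect_gt(nrow(tr), 10L)
  expect_identical(oracleVerifyGreedy(m, tr), nrow(tr))
  expect_lte(nrow(meshFaces(got)), 40L)
})

test_that("each interior collapse removes exactly two faces", {
  f <- sphereField(4, 11, 11)
  m <- extractSurface(f)
  n0 <- nrow(meshFaces(m))
  out <- decimateMesh(m, simplifyConfig(targetFaces = n0 - 20L), trace = TRUE)
  expect_identical(nrow(meshFaces(out)),
                   n0 - 2L * nrow(attr(out, "collapses")))
})

test_that("decimation preserves watertightness, topology and volume", {
  f <- sphereField(10, 36, 26)
  m <- extractSurface(f)
  st0 <- meshStats(m)
  out <- decimateMesh(m, simplifyConfig(targetRatio = 0.2))
  st <- meshStats(out)
  expect_lte(st$nFaces, ceiling(0.2 * st0$nFaces))
  expect_true(st$watertight)
  expect_identical(st$eulerCharacteristic, 2L)
  expect_lt(abs(st$enclosedVolume - st0$enclosedVolume) / st0$enclosedVolume,
            0.05)
})
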