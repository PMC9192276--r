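squareContour <- function(slice = 3L) {
  contourSet(list(list(
    index = slice,
    polygons = list(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
  )))
}

test_that("voxels are classified against contours as outside/on/inside", {
  cs <- squareContour(4L)   # slice index 4 => world z = 3 with unit spacing
  f <- classifyVoxels(c(16, 16, 8), c(1, 1, 1), c(0, 0, 0), cs,
                      onTolerance = 0.01)
  lab <- fieldLabels(f)
  expect_identical(lab[6, 6, 4], 1L)      # (5, 5) inside the square
  expect_identical(lab[16, 6, 4], -1L)    # (15, 5) outside all contours
  expect_identical(lab[11, 6, 4], 0L)     # (10, 5) on the boundary
  expect_identical(lab[1, 1, 4], 0L)      # corner of the square
  # slices without polygons are entirely outside
  expect_true(all(lab[, , -4] == -1L))
  # exhaustiveness: one label per voxel, nothing else
  expect_true(all(lab %in% c(-1L, 0L, 1L)))
})

test_that("exact boundary hits are labeled 0 even with zero tolerance", {
  f <- classifyVoxels(c(16, 16, 8), c(1, 1, 1), c(0, 0, 0), squareContour(4L))
  lab <- fieldLabels(f)
  expect_identical(lab[11, 6, 4], 0L)
  expect_identical(lab[6, 6, 4], 1L)
})

test_that("growing the on-tolerance never turns an on-voxel off", {
  cs <- squareContour(2L)
  tols <- c(0, 0.25, 0.5, 1, 2)
  prev <- NULL
  for (tol in tols) {
    lab <- fieldLabels(classifyVoxels(c(14, 14, 4), c(1, 1, 1), c(0, 0, 0),
                                      cs, onTolerance = tol))
    if (!is.null(prev)) expect_true(all(lab[prev == 0L] == 0L))
    prev <- lab
  }
})

test_that("even-odd rule empties nested lumens, any-rule fills them", {
  outer <- rbind(c(-8, -8), c(8, -8), c(8, 8), c(-8, 8))
  inner <- rbind(c(-4, -4), c(4, -4), c(4, 4), c(-4, 4))
  cs <- contourSet(list(list(index = 2L, polygons = list(outer, inner))))
  geom <- list(dims = c(19, 19, 3), sp = c(1, 1, 1), or = c(-9, -9, 0))
  evenodd <- fieldLabels(classifyVoxels(geom$dims, geom$sp, geom$or, cs))
  anyrule <- fieldLabels(classifyVoxels(geom$dims, geom$sp, geom$or, cs,
                                        rule = "any"))
  ctr <- c(10, 10, 2)                      # world (0, 0): inside both rings
  wall <- c(16, 10, 2)                     # world (6, 0): between the rings
  expect_identical(evenodd[ctr[1], ctr[2], ctr[3]], -1L)
  expect_identical(anyrule[ctr[1], ctr[2], ctr[3]], 1L)
  expect_identical(evenodd[wall[1], wall[2], wall[3]], 1L)
  expect_identical(anyrule[wall[1], wall[2], wall[3]], 1L)
})

test_that("contour slice indices outside the grid raise an error", {
  expect_error(
    classifyVoxels(c(8, 8, 4), c(1, 1, 1), c(0, 0, 0), squareContour(9L)),
    "outside the grid")
})

test_that("implicit classification maps sign with a zero tolerance band", {
  g <- voxelGrid(array(c(-2, 0, 3, 1, -1, 2, 0.5, -3), c(2, 2, 2)))
  expect_identical(as.vector(fieldLabels(classifyImplicit(g))),
                   c(-1L, 0L, 1L, 1L, -1L, 1L, 1L, -1L))
  expect_identical(as.vector(fieldLabels(classifyImplicit(g, 0.6))),
                   c(-1L, 0L, 1L, 1L, -1L, 1L, 0L, -1L))
  allpos <- voxelGrid(array(1, c(2, 2, 2)))
  expect_true(all(fieldLabels(classifyImplicit(allpos)) == 1L))
  expect_error(classifyImplicit(g, -1), ">= 0")
})

test_that("inside-voxel count of a classified sphere approaches its volume", {
  f <- sphereField(radius = 10, n = 64, extent = 32)
  vol <- sum(fieldLabels(f) == 1L) * prod(gridSpacing(f))
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
})

indexToWorldHelper <- function(idx, sp, orig) {
  sweep(sweep(idx - 1, 2, sp, "*"), 2, orig, "+")
}

test_that("contour and implicit routes agree away from the boundary", {
  ph <- makeSpherePhantom(10)
  n <- 48; sp <- rep(0.7, 3); orig <- -(n - 1) * sp / 2
  g <- voxelize(ph, rep(n, 3), sp, orig)
  fi <- fieldLabels(classifyImplicit(g))
  fc <- fieldLabels(classifyVoxels(rep(n, 3), sp, orig, contoursFromGrid(g)))
  differ <- which(fi != fc, arr.ind = TRUE)
  if (nrow(differ) > 0) {
    # disagreements may only sit within one in-slice cell of the surface
    w <- indexToWorldHelper(differ, sp, orig)
    dev <- abs(sqrt(rowSums(w^2)) - 10)
    expect_lt(max(dev), sqrt(2) * max(sp))
  }
  expect_lt(nrow(differ) / length(fi), 0.01)
})
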