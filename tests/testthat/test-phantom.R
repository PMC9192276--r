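test_that("sphere phantom carries closed-form ground truth", {
  ph <- makeSpherePhantom(10)
  expect_equal(ph@analyticVolume, 4 / 3 * pi * 1000)
  expect_equal(ph@analyticArea, 4 * pi * 100)
  expect_equal(makeSpherePhantom(1)@analyticVolume, 4 * pi / 3)
  # signed pseudo-distance: positive inside, negative outside, zero on
  expect_equal(ph@implicitFn(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 12, 0))),
               c(10, 0, -2))
  expect_error(makeSpherePhantom(0), "positive")
  expect_error(makeSpherePhantom(-3), "positive")
})

test_that("voxelize samples the implicit function at voxel centers", {
  ph <- makeSpherePhantom(10)
  g <- voxelize(ph, c(64, 64, 64), c(1, 1, 1), c(-31.5, -31.5, -31.5))
  v <- gridValues(g)
  expect_identical(dim(v), c(64L, 64L, 64L))
  expect_true(v[32, 32, 32] > 0)    # near the center
  expect_true(v[1, 1, 1] < 0)       # a corner
  # centered sphere: field symmetric under index reflection
  expect_equal(v, v[64:1, 64:1, 64:1])
  # size contract at the minimum grid
  g2 <- voxelize(ph, c(2, 2, 2))
  expect_identical(length(gridValues(g2)), 8L)
  expect_error(voxelize(ph, c(1, 4, 4)), ">= 2")
  expect_error(voxelize(ph, c(4, 4, 4), spacing = c(0, 1, 1)), "positive")
})

test_that("bladder phantom is deterministic and rejects infeasible lesions", {
  p1 <- makeBladderPhantom(lesionCount = 2, seed = 7)
  p2 <- makeBladderPhantom(lesionCount = 2, seed = 7)
  co <- cbind(runif(50, -40, 40), runif(50, -35, 35), runif(50, -30, 30))
  expect_identical(p1@implicitFn(co), p2@implicitFn(co))
  expect_identical(attr(p1, "lesionCenters"), attr(p2, "lesionCenters"))
  expect_true(p1@approximate)
  expect_error(makeBladderPhantom(lesionRadius = 50), "lumen")
  expect_error(makeBladderPhantom(wallThickness = 0), "positive")
  expect_error(makeBladderPhantom(outerRadii = c(40, 35, 3), wallThickness = 4),
               "wall thickness")
})

test_that("bladder phantom with no lesions is a pure two-component shell", {
  ph <- makeBladderPhantom(lesionCount = 0)
  g <- voxelize(ph, c(48, 48, 40), c(1.85, 1.65, 1.6), c(-43.5, -39, -31.2))
  st <- meshStats(extractSurface(classifyImplicit(g)))
  expect_true(st$watertight)
  # two nested genus-0 components: chi = 2 + 2
  expect_identical(st$eulerCharacteristic, 4L)
})

test_that("seeded lesions appear as the requested number of lumen masses", {
  ph <- makeBladderPhantom(lesionCount = 2, seed = 7)
  inner <- c(40, 35, 30) - 4
  g <- voxelize(ph, c(72, 64, 56), c(1.2, 1.18, 1.16), c(-42.6, -37.2, -31.9))
  co <- expand.grid(x = seq_len(72), y = seq_len(64), z = seq_len(56))
  wx <- -42.6 + (co$x - 1) * 1.2
  wy <- -37.2 + (co$y - 1) * 1.18
  wz <- -31.9 + (co$z - 1) * 1.16
  inLumen <- (wx / inner[1])^2 + (wy / inner[2])^2 + (wz / inner[3])^2 < 1
  mask <- array(gridValues(g) > 0 & inLumen, dim = c(72, 64, 56))
  expect_identical(countComponents(mask), 2L)
})

test_that("inside-voxel counting converges to the analytic volume", {
  ph <- makeSpherePhantom(10)
  err <- vapply(c(24, 48), function(n) {
    sp <- rep(24 / (n - 1), 3)
    g <- voxelize(ph, rep(n, 3), sp, -(n - 1) * sp / 2)
    abs(sum(gridValues(g) > 0) * prod(sp) - ph@analyticVolume)
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("quadrature ground truth matches the sphere's closed forms", {
  ph <- makeSpherePhantom(10)
  gt <- implicitGroundTruth(ph@implicitFn, rep(-13, 3), rep(13, 3), 0.5)
  expect_lt(abs(gt$volume - ph@analyticVolume) / ph@analyticVolume, 0.02)
  expect_lt(abs(gt$area - ph@analyticArea) / ph@analyticArea, 0.02)
})

test_that("slice contours trace the analytic cross-section", {
  ph <- makeSpherePhantom(10)
  n <- 64; sp <- rep(0.5, 3); orig <- -(n - 1) * sp / 2
  g <- voxelize(ph, rep(n, 3), sp, orig)
  cs <- contoursFromGrid(g)
  zidx <- round(-orig[3] / sp[3]) + 1
  sl <- Filter(function(s) s$index == zidx, cs@slices)[[1]]
  expect_length(sl$polygons, 1L)
  p <- sl$polygons[[1]]
  zc <- orig[3] + (zidx - 1) * sp[3]
  expect_lt(abs(abs(shoelace(p)) - pi * (100 - zc^2)) / (pi * (100 - zc^2)),
            0.05)
  expect_gt(shoelace(p), 0)                     # counterclockwise
  expect_false(all(p[1, ] == p[nrow(p), ]))     # implicit closure
  # every contour vertex lies close to the analytic iso-surface
  maxdev <- max(abs(vapply(cs@slices, function(s) {
    z <- orig[3] + (s$index - 1) * sp[3]
    max(abs(vapply(s$polygons, function(q) {
      max(abs(sqrt(q[, 1]^2 + q[, 2]^2 + z^2) - 10))
    }, numeric(1))))
  }, numeric(1))))
  expect_lt(maxdev, sqrt(2) * max(sp))          # within one in-slice cell
  # slices entirely outside the sphere carry no polygons
  expect_false(any(vapply(cs@slices, function(s) {
    abs(orig[3] + (s$index - 1) * sp[3]) > 10
  }, logical(1))))
})

test_that("annular slices give two nested contours and flat slices error", {
  ph <- makeBladderPhantom(lesionCount = 0)
  g <- voxelize(ph, c(64, 64, 48), c(1.4, 1.25, 1.34), c(-44.1, -39.4, -31.5))
  cs <- contoursFromGrid(g)
  mid <- Filter(function(s) abs(-31.5 + (s$index - 1) * 1.34) < 1, cs@slices)
  expect_true(all(vapply(mid, function(s) length(s$polygons), integer(1)) == 2L))
  flat <- voxelGrid(array(0, c(4, 4, 4)))
  expect_error(contoursFromGrid(flat), "ambiguous")
})

test_that("contour sets and volumes round-trip through JSON and NIfTI", {
  ph <- makeSpherePhantom(8)
  g <- voxelize(ph, c(24, 24, 24), c(0.8, 0.8, 0.8), c(-9.2, -9.2, -9.2))
  cs <- contoursFromGrid(g)
  tf <- tempfile(fileext = ".json")
  writeContours(cs, tf)
  cs2 <- readContours(tf)
  expect_identical(cs2@sliceAxis, cs@sliceAxis)
  expect_equal(cs2@slices, cs@slices, tolerance = 1e-12)
  tv <- tempfile(fileext = ".nii.gz")
  writeVolume(g, tv)
  g2 <- readVolume(tv)
  # NIfTI stores samples and the sform as 32-bit floats
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-6)
  expect_equal(gridSpacing(g2), gridSpacing(g), tolerance = 1e-6)
  expect_equal(gridOrigin(g2), gridOrigin(g), tolerance = 1e-6)
  f <- classifyImplicit(g)
  tw <- tempfile(fileext = ".nii.gz")
  writeVolume(f, tw)
  f2 <- readVolume(tw, as = "field")
  expect_identical(fieldLabels(f2), fieldLabels(f))
})
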