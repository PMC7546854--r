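# Volume data model, NIfTI round trips, grid generation, tent-kernel samplers

test_that("NIfTI round trip preserves data, spacing and origin", {
  v <- Volume(array(7, c(8, 8, 8)), spacing = c(5, 1, 1), origin = c(2, 3, 4))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(v, p)
  r <- readVolume(p)
  expect_equal(volData(r), volData(v))
  expect_equal(voxelSpacing(r), c(5, 1, 1))
  expect_equal(volOrigin(r), c(2, 3, 4), tolerance = 1e-6)

  m <- Mask(array(as.numeric(array(runif(8^3), c(8, 8, 8)) > 0.5), c(8, 8, 8)),
            spacing = c(2, 1.5, 1))
  pm <- withr::local_tempfile(fileext = ".nii.gz")
  writeVolume(m, pm)
  rm_ <- readVolume(pm, mask = TRUE)
  expect_s4_class(rm_, "Mask")
  expect_equal(volData(rm_), volData(m))
})

test_that("unreadable and unsupported inputs raise clear errors", {
  p <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti", p)
  expect_error(readVolume(p), "nii")
  expect_error(readVolume(file.path(tempdir(), "absent-volume.nii.gz")),
               "absent-volume")
  # 4D input with a non-trivial 4th dimension is rejected
  p4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 3))), p4)
  expect_error(readVolume(p4), "dimension")
})

test_that("volume validity enforces the geometry contract", {
  expect_error(Volume(array(1, c(1, 4, 4))), "at least 2")
  expect_error(Volume(array(1, c(4, 4, 4)), spacing = c(0, 1, 1)), "spacing")
  expect_error(Volume(array(c(NA, rep(1, 63)), c(4, 4, 4))), "finite")
  expect_error(Mask(array(2, c(4, 4, 4))), "0 or 1")
})

test_that("bilinear sampling follows the tent-kernel sum", {
  # hand-evaluated single point: four neighbours, weight 1/4 each
  U <- matrix(c(0, 2, 1, 3), 2, 2)  # rows y: (0,1) / (2,3)
  expect_identical(bilinearSample(U, cbind(0.5, 0.5)), 1.5)
  # all kernel weights vanish far outside
  expect_identical(bilinearSample(U, cbind(-2, -2)), 0)
  # identity grid reproduces any image bit-exactly
  img <- matrix(rnorm(16 * 16), 16, 16)
  expect_identical(bilinearSample(img, identityGrid(dim(img))), img)
  # random images against the literal double sum
  set.seed(10)
  for (rep in 1:5) {
    img <- matrix(rnorm(16 * 16), 16, 16)
    pts <- cbind(runif(25, -2, 17), runif(25, -2, 17))
    expect_equal(bilinearSample(img, pts), naiveBilinear(img, pts),
                 tolerance = 1e-6)
  }
})

test_that("trilinear sampling matches a direct per-point kernel loop", {
  set.seed(11)
  A <- array(rnorm(5^3), c(5, 5, 5))
  pts <- cbind(runif(20, 0, 4), runif(20, 0, 4), runif(20, 0, 4))
  expect_equal(trilinearSample(A, pts), naiveTrilinear(A, pts),
               tolerance = 1e-10)
  # identity grid is bit-exact
  v <- Volume(array(rnorm(4 * 6 * 5), c(4, 6, 5)))
  expect_identical(volData(trilinearSample(v, identityGrid(c(4, 6, 5)))),
                   volData(v))
  # partition of unity: constant volume stays constant strictly inside
  cv <- array(3.7, c(6, 6, 6))
  inner <- cbind(runif(30, 0, 5), runif(30, 0, 5), runif(30, 0, 5))
  expect_equal(trilinearSample(cv, inner), rep(3.7, 30), tolerance = 1e-12)
})

test_that("sampler gradient matches central finite differences", {
  set.seed(12)
  A <- array(rnorm(6 * 7 * 8), c(6, 7, 8))
  pts <- cbind(runif(15, 0.3, 6.3), runif(15, 0.3, 5.3), runif(15, 0.3, 4.3))
  g <- sampleGradient(A, pts)
  eps <- 1e-5
  for (k in 1:3) {
    pp <- pts; pp[, k] <- pp[, k] + eps
    pm <- pts; pm[, k] <- pm[, k] - eps
    fd <- (trilinearSample(A, pp) - trilinearSample(A, pm)) / (2 * eps)
    expect_equal(g[, k], fd, tolerance = 1e-4)
  }
  # 2D path
  U <- matrix(rnorm(15 * 15), 15, 15)
  pts2 <- cbind(runif(10, 0.3, 13.3), runif(10, 0.3, 13.3))
  g2 <- sampleGradient(U, pts2)
  for (k in 1:2) {
    pp <- pts2; pp[, k] <- pp[, k] + eps
    pm <- pts2; pm[, k] <- pm[, k] - eps
    fd <- (bilinearSample(U, pp) - bilinearSample(U, pm)) / (2 * eps)
    expect_equal(g2[, k], fd, tolerance = 1e-4)
  }
})

test_that("field-to-grid generation honours the displacement contract", {
  # zero field: identity grid
  f <- identityField(c(4, 4, 4), c(2, 2, 2))
  g <- fieldToGrid(f, c(4, 4, 4))
  expect_equal(g@points, identityGrid(c(4, 4, 4))@points)
  # uniform displacement shifts every coordinate by exactly that amount
  f@control[, , , 3] <- 1
  gx <- fieldToGrid(f, c(4, 4, 4))
  expect_equal(gx@points[, "x"], identityGrid(c(4, 4, 4))@points[, "x"] + 1,
               tolerance = 1e-12)
  # single displaced control point: dense field matches the direct
  # interpolation oracle at every voxel
  f2 <- identityField(c(6, 9, 9), c(2, 4, 4))
  f2@control[2, 2, 2, 2] <- 1.5
  f2@control[2, 2, 2, 3] <- -0.75
  dense <- denseField(f2, c(6, 9, 9))
  oracle <- naiveLatticeInterp(f2@control, c(6, 9, 9), c(2, 4, 4))
  expect_equal(dense, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  # mismatched lattice is a geometry error
  expect_error(denseField(identityField(c(4, 4, 4), c(2, 2, 2)), c(32, 32, 32)),
               "geometry")
})
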