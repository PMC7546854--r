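# Siamese localizer, pairwise optimisation, landmark error

test_that("zero-initialised localizer proposes the identity field", {
  set.seed(30)
  v <- Volume(array(runif(8 * 32 * 32), c(8, 32, 32)), c(5, 1, 1))
  w <- Volume(array(runif(8 * 32 * 32), c(8, 32, 32)), c(5, 1, 1))
  cfg <- registrationConfig(featureLevels = 3L, blockPartition = c(1, 2, 2),
                            seed = 5)
  f <- siameseLocalize(v, w, cfg)
  expect_true(all(f@control == 0))
  # deterministic with a random head, and twin branches share weights:
  # identical inputs through either branch produce identical encodings
  cfgR <- registrationConfig(featureLevels = 3L, blockPartition = c(1, 2, 2),
                             seed = 5, headInit = "random")
  f1 <- siameseLocalize(v, w, cfgR)
  f2 <- siameseLocalize(v, w, cfgR)
  expect_identical(f1@control, f2@control)
  expect_true(any(f1@control != 0))
  # geometry mismatch is rejected
  u <- Volume(array(0.5, c(8, 16, 16)), c(5, 1, 1))
  expect_error(siameseLocalize(v, u, cfg), "geometry")
})

test_that("swapped inputs give finite (not necessarily symmetric) fields", {
  ph <- smallPhantom()
  cfg <- smallRegConfig(maxIters = 2L)
  fwd <- registerPair(ph$moving, ph$fixed, cfg)
  bwd <- registerPair(ph$fixed, ph$moving, cfg)
  expect_true(all(is.finite(denseField(resultField(fwd)))))
  expect_true(all(is.finite(denseField(resultField(bwd)))))
})

test_that("an already-aligned pair stays at the identity", {
  set.seed(31)
  v <- Volume(array(runif(12 * 32 * 32), c(12, 32, 32)), c(5, 1, 1))
  cfg <- registrationConfig(featureLevels = 3L, blockPartition = c(1, 2, 2),
                            controlSpacing = c(4, 8, 8), maxIters = 5L, seed = 5)
  rr <- registerPair(v, v, cfg)
  meanDisp <- mean(sqrt(rowSums(matrix(denseField(resultField(rr)), ncol = 3)^2)))
  expect_lt(meanDisp, 0.1)
  expect_equal(min(lossTrace(rr)), rr@initialLoss, tolerance = 1e-9)
})

test_that("iteration budget and determinism contracts hold", {
  ph <- smallPhantom()
  cfg1 <- smallRegConfig(maxIters = 1L, translationInit = FALSE)
  rr1 <- registerPair(ph$moving, ph$fixed, cfg1)
  expect_identical(rr1@iterations, 1L)
  expect_length(lossTrace(rr1), 1L)

  cfg <- smallRegConfig(maxIters = 4L)
  ra <- registerPair(ph$moving, ph$fixed, cfg)
  rb <- registerPair(ph$moving, ph$fixed, cfg)
  expect_identical(lossTrace(ra), lossTrace(rb))
  expect_identical(denseField(resultField(ra)), denseField(resultField(rb)))
})

test_that("registration improves the alignment of a deformed phantom", {
  ph <- smallPhantom(seed = 5)
  sp <- voxelSpacing(ph$moving)
  base <- landmarkError(zeroDenseField(dim(volData(ph$moving))), ph$landmarks, sp)
  rr <- registerPair(ph$moving, ph$fixed, smallRegConfig(maxIters = 10L,
                                                         tolerance = 1e-7))
  post <- landmarkError(resultField(rr), ph$landmarks, sp)
  expect_lt(post$meanMM, base$meanMM)
  # best loss never exceeds the identity-field loss
  expect_lte(min(lossTrace(rr)), rr@initialLoss + 1e-9)
})

test_that("landmark error follows its analytic definition", {
  idf <- identityField(c(8, 32, 32), c(2, 8, 8))
  # coincident landmarks: zero error
  pts <- cbind(c(10, 20, 15), c(10, 20, 12), c(10, 20, 18))
  expect_equal(landmarkError(idf, LandmarkSet(pts, pts), c(5, 1, 1))$meanMM, 0)
  # 3 mm offset along one axis: mean 3, sd 0
  off <- pts; off[, 3] <- off[, 3] + 3
  le <- landmarkError(idf, LandmarkSet(off, pts), c(5, 1, 1))
  expect_equal(le$meanMM, 3)
  expect_equal(le$sdMM, 0)
  # truth field evaluated on its own landmarks: interpolation error only,
  # well under half a voxel diagonal
  ph <- smallPhantom()
  sp <- voxelSpacing(ph$moving)
  self <- landmarkError(ph$truthField, ph$landmarks, sp)
  expect_lt(self$meanMM, 0.5 * sqrt(sum(sp^2)))
  # landmarks outside the extent are rejected
  bad <- pts; bad[1, 1] <- 1e4
  expect_error(landmarkError(idf, LandmarkSet(bad, bad), c(5, 1, 1)), "extent")
  expect_error(LandmarkSet(pts[0, , drop = FALSE], pts[0, , drop = FALSE]),
               "at least one")
})

test_that("2d slice-wise mode keeps the through-slice component at zero", {
  set.seed(33)
  co <- ablamark:::coordArrays(c(6, 32, 32), c(5, 1, 1))
  a <- array(0.2, c(6, 32, 32))
  for (i in 1:6) {  # smooth bright blobs give the similarity something to see
    cen <- c(runif(1, 5, 25), runif(1, 6, 24), runif(1, 6, 24))
    a <- a + 0.8 * exp(-(((co$Z - cen[1]) / 6)^2 + ((co$Y - cen[2]) / 3)^2 +
                           ((co$X - cen[3]) / 3)^2))
  }
  mov <- Volume(a, c(5, 1, 1))
  # in-plane shift of every slice by 2 voxels in x
  b <- a
  b[, , 1:30] <- a[, , 3:32]
  fx <- Volume(b, c(5, 1, 1))
  cfg <- registrationConfig(mode = "2d", featureLevels = 3L,
                            blockPartition = c(2, 2), controlSpacing = c(2, 8, 8),
                            maxIters = 6L, seed = 5)
  rr <- registerPair(mov, fx, cfg)
  d <- denseField(resultField(rr))
  expect_true(all(d[, , , 1] == 0))
  # the recovered in-plane x displacement matches the simulated shift
  expect_gt(mean(d[, 5:28, 5:28, 3]), 1.5)
})
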