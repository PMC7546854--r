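# Mask warping, minimal ablative margin, safety classification, dilation

test_that("identity field leaves a mask untouched; integer shifts are exact", {
  m <- Mask(array(0, c(8, 16, 16)))
  m@data[3:5, 6:9, 6:9] <- 1
  idf <- identityField(c(8, 16, 16), c(2, 4, 4))
  expect_identical(volData(warpMask(m, idf)), volData(m))
  # uniform integer-voxel translation preserves shape and volume
  f <- identityField(c(8, 16, 16), c(2, 4, 4))
  f@control[, , , 3] <- 2
  wm <- warpMask(m, f)
  expect_equal(sum(volData(wm)), sum(volData(m)))
  expect_identical(volData(wm)[, , 4:7], volData(m)[, , 6:9])
})

test_that("warped-mask volume tracks the field Jacobian", {
  m <- sphereMask(c(24, 24, 24), c(1, 1, 1), c(11.5, 11.5, 11.5), 7)
  f <- identityField(c(24, 24, 24), c(6, 6, 6))
  set.seed(40)
  f@control <- array(rnorm(length(f@control), sd = 0.6), dim(f@control))
  wm <- warpMask(m, f)
  # numeric Jacobian determinant of x -> x + u(x) on the voxel grid
  d <- denseField(f, c(24, 24, 24))
  J <- array(1, c(24, 24, 24))
  grad <- function(comp, ax) {
    g <- array(0, c(24, 24, 24))
    idx <- 2:23
    if (ax == 1) g[idx, , ] <- (comp[idx + 1, , ] - comp[idx - 1, , ]) / 2
    if (ax == 2) g[, idx, ] <- (comp[, idx + 1, ] - comp[, idx - 1, ]) / 2
    if (ax == 3) g[, , idx] <- (comp[, , idx + 1] - comp[, , idx - 1]) / 2
    g
  }
  Jm <- array(0, c(24, 24, 24, 3, 3))
  for (i in 1:3) for (j in 1:3)
    Jm[, , , i, j] <- (i == j) + grad(d[, , , i], j)
  detJ <- Jm[, , , 1, 1] * (Jm[, , , 2, 2] * Jm[, , , 3, 3] - Jm[, , , 2, 3] * Jm[, , , 3, 2]) -
    Jm[, , , 1, 2] * (Jm[, , , 2, 1] * Jm[, , , 3, 3] - Jm[, , , 2, 3] * Jm[, , , 3, 1]) +
    Jm[, , , 1, 3] * (Jm[, , , 2, 1] * Jm[, , , 3, 2] - Jm[, , , 2, 2] * Jm[, , , 3, 1])
  # pull-back: each warped voxel covers det(I + Du) source volume
  predicted <- sum(volData(wm) * detJ)
  expect_lt(abs(predicted - sum(volData(m))) / sum(volData(m)), 0.1)
})

test_that("minimal margin matches analytic geometry on concentric spheres", {
  cen <- c(23.5, 23.5, 23.5)
  tum <- sphereMask(c(48, 48, 48), c(1, 1, 1), cen, 10)
  abl <- sphereMask(c(48, 48, 48), c(1, 1, 1), cen, 15)
  mr <- minimalMargin(tum, abl)
  expect_lt(abs(minMargin(mr) - 5), sqrt(3))
  expect_identical(marginGroup(mr), "A")  # 5 mm is the inclusive boundary
  expect_true(isCovered(mr))
})

test_that("coincident and protruding tumours floor the margin at zero", {
  m <- sphereMask(c(20, 20, 20), c(1, 1, 1), c(9.5, 9.5, 9.5), 6)
  same <- minimalMargin(m, m)
  expect_equal(minMargin(same), 0)
  expect_true(isCovered(same))
  # tumour sticking out of the ablation zone
  abl <- sphereMask(c(20, 20, 20), c(1, 1, 1), c(9.5, 9.5, 5.5), 6)
  out <- minimalMargin(m, abl)
  expect_equal(minMargin(out), 0)
  expect_false(isCovered(out))
  expect_true(any(surfaceDistances(out) < 0))
  # empty masks are rejected
  empty <- Mask(array(0, c(20, 20, 20)))
  expect_error(minimalMargin(empty, m), "empty tumor")
  expect_error(minimalMargin(m, empty), "empty ablation")
})

test_that("margin grouping uses the inclusive 5-mm boundary", {
  expect_identical(classifyMargin(5.0), "A")
  expect_identical(classifyMargin(5.1), "B")
  expect_identical(classifyMargin(0.0), "A")
  expect_identical(classifyMargin(4, thresholdMM = 3), "B")
  expect_error(classifyMargin(-1), "validation")
})

test_that("minimal margin agrees with the all-pairs boundary oracle", {
  for (seed in 1:4) {
    tum <- randomBlobMask(c(24, 24, 24), c(1.5, 1, 1), nSpheres = 2,
                          rRange = c(3, 6), seed = seed)
    abl <- randomBlobMask(c(24, 24, 24), c(1.5, 1, 1), nSpheres = 3,
                          rRange = c(5, 9), seed = seed + 100)
    if (sum(tum) == 0 || sum(abl) == 0) next
    mr <- minimalMargin(Mask(tum, c(1.5, 1, 1)), Mask(abl, c(1.5, 1, 1)))
    oracle <- bruteMarginOracle(tum, abl, c(1.5, 1, 1))
    expect_equal(minMargin(mr), oracle$minMargin,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(sort(surfaceDistances(mr)), sort(oracle$signed),
                 tolerance = 1e-9)
  }
})

test_that("margin is monotone under dilation and rigid-shift invariant", {
  tum <- sphereMask(c(28, 28, 28), c(1, 1, 1), c(13.5, 13.5, 13.5), 5)
  abl <- sphereMask(c(28, 28, 28), c(1, 1, 1), c(13.5, 13.5, 13.5), 10)
  m0 <- minMargin(minimalMargin(tum, abl))
  ablBig <- theoreticalMarginContour(abl, 2)
  expect_gte(minMargin(minimalMargin(tum, ablBig)), m0)
  tumBig <- theoreticalMarginContour(tum, 2)
  expect_lte(minMargin(minimalMargin(tumBig, abl)), m0)
  # translating both masks together leaves the result unchanged
  shift <- function(a, k) {
    b <- array(0, dim(a)); b[, , (1 + k):dim(a)[3]] <- a[, , 1:(dim(a)[3] - k)]
    b
  }
  mrS <- minimalMargin(Mask(shift(volData(tum), 3)), Mask(shift(volData(abl), 3)))
  expect_equal(minMargin(mrS), m0, tolerance = 1e-9)
})

test_that("theoretical margin contour is a spacing-aware ball dilation", {
  tum <- sphereMask(c(44, 44, 44), c(1, 1, 1), c(21.5, 21.5, 21.5), 10)
  dil <- theoreticalMarginContour(tum, 5)
  co <- ablamark:::coordArrays(c(44, 44, 44), c(1, 1, 1))
  r <- sqrt((co$Z - 21.5)^2 + (co$Y - 21.5)^2 + (co$X - 21.5)^2)
  expect_lt(abs(max(r[volData(dil) == 1]) - 15), sqrt(3))
  # strictly contains the tumour
  expect_true(all(volData(dil)[volData(tum) == 1] == 1))
  expect_gt(sum(volData(dil)), sum(volData(tum)))
  # sub-voxel margins add at most a one-voxel shell
  tiny <- theoreticalMarginContour(tum, 0.25)
  shell <- sum(volData(tiny)) - sum(volData(tum))
  expect_gt(shell, 0)
  expect_lte(max(ablamark:::cppEDTFromSeeds(as.vector(volData(tum) == 1),
                                            c(44L, 44L, 44L), c(1, 1, 1))[volData(tiny) == 1]), 1)
  # single voxel dilates to the discrete ball of the requested radius
  one <- Mask(array(0, c(15, 15, 15)), c(2, 1, 1))
  one@data[8, 8, 8] <- 1
  ball <- theoreticalMarginContour(one, 3)
  co2 <- ablamark:::coordArrays(c(15, 15, 15), c(2, 1, 1))
  within <- (co2$Z - 14)^2 + (co2$Y - 7)^2 + (co2$X - 7)^2 <= 9 + 1e-9
  expect_identical(volData(ball) == 1, within)
  # nesting: smaller margins give subsets
  d2 <- theoreticalMarginContour(tum, 2)
  d4 <- theoreticalMarginContour(tum, 4)
  expect_true(all(volData(d4)[volData(d2) == 1] == 1))
  expect_error(theoreticalMarginContour(tum, 0), "validation")
})

test_that("margin sufficiency chains warp, margin and grouping", {
  cen <- c(15.5, 15.5, 15.5)
  tum <- sphereMask(c(32, 32, 32), c(1, 1, 1), cen, 5)
  abl7 <- sphereMask(c(32, 32, 32), c(1, 1, 1), cen, 12)  # 7 mm gap
  abl3 <- sphereMask(c(32, 32, 32), c(1, 1, 1), cen, 8)   # 3 mm gap
  idf <- identityField(c(32, 32, 32), c(4, 4, 4))
  expect_true(marginSufficiency(tum, abl7, idf)$achieved)
  expect_false(marginSufficiency(tum, abl3, idf)$achieved)
  # a 4 mm translation toward the boundary destroys a 7 mm gap
  f <- identityField(c(32, 32, 32), c(4, 4, 4))
  f@control[, , , 3] <- -4  # pull-back: tumour appears shifted +4 in x
  res <- marginSufficiency(tum, abl7, f)
  expect_false(res$achieved)
  expect_lt(minMargin(res$margin), 5)
})
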