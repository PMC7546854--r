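# Independent brute-force oracles used to freeze expected values. These stay
# deliberately naive (explicit loops, all-pairs scans) and share no code with
# the package internals they check.

# tent-kernel sampling as a literal double sum over every source pixel
naiveBilinear <- function(U, pts) {
  ny <- nrow(U); nx <- ncol(U)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]
    acc <- 0
    for (n in 0:(ny - 1)) for (m in 0:(nx - 1))
      acc <- acc + U[n + 1, m + 1] * max(0, 1 - abs(x - m)) * max(0, 1 - abs(y - n))
    out[i] <- acc
  }
  out
}

# separable 3-axis tent kernel, literal triple sum
naiveTrilinear <- function(A, pts) {
  d <- dim(A)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    x <- pts[i, 1]; y <- pts[i, 2]; z <- pts[i, 3]
    acc <- 0
    for (iz in 0:(d[1] - 1)) for (iy in 0:(d[2] - 1)) for (ix in 0:(d[3] - 1))
      acc <- acc + A[iz + 1, iy + 1, ix + 1] *
        max(0, 1 - abs(z - iz)) * max(0, 1 - abs(y - iy)) * max(0, 1 - abs(x - ix))
    out[i] <- acc
  }
  out
}

# direct per-voxel cubic (Keys, a = -1/2) interpolation of a control lattice
naiveKeysWeights <- function(f) {
  c(0.5 * (-f^3 + 2 * f^2 - f), 0.5 * (3 * f^3 - 5 * f^2 + 2),
    0.5 * (-3 * f^3 + 4 * f^2 + f), 0.5 * (f^3 - f^2))
}

naiveLatticeInterp <- function(control, outDims, spacingVox) {
  nd <- dim(control)[1:3]
  out <- array(0, c(outDims, 3))
  axw <- function(i, sp, nc) {
    u <- i / sp; j0 <- floor(u); f <- u - j0
    idx <- pmin(pmax(j0 - 1 + 0:3, 0), nc - 1) + 1
    list(idx = idx, w = naiveKeysWeights(f))
  }
  for (iz in 0:(outDims[1] - 1)) for (iy in 0:(outDims[2] - 1))
    for (ix in 0:(outDims[3] - 1)) {
      az <- axw(iz, spacingVox[1], nd[1])
      ay <- axw(iy, spacingVox[2], nd[2])
      ax <- axw(ix, spacingVox[3], nd[3])
      for (k in 1:3) {
        acc <- 0
        for (a in 1:4) for (b in 1:4) for (cc in 1:4)
          acc <- acc + az$w[a] * ay$w[b] * ax$w[cc] *
            control[az$idx[a], ay$idx[b], ax$idx[cc], k]
        out[iz + 1, iy + 1, ix + 1, k] <- acc
      }
    }
  out
}

# boundary voxels by explicit neighbour scan (edges count as background)
naiveBoundary <- function(a) {
  d <- dim(a)
  idx <- which(a == 1, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    p <- idx[i, ]
    for (ax in 1:3) for (s in c(-1, 1)) {
      q <- p; q[ax] <- q[ax] + s
      if (q[ax] < 1 || q[ax] > d[ax] || a[q[1], q[2], q[3]] == 0) {
        keep[i] <- TRUE
      }
    }
  }
  idx[keep, , drop = FALSE]
}

# all-pairs signed surface distances: for each tumour boundary voxel the
# distance (mm) to the nearest ablation boundary voxel, signed by ablation
# membership
bruteMarginOracle <- function(tumor, ablation, spacing) {
  tb <- naiveBoundary(tumor)
  ab <- naiveBoundary(ablation)
  tmm <- sweep(tb - 1, 2, spacing, "*")
  amm <- sweep(ab - 1, 2, spacing, "*")
  d <- sqrt(outer(rowSums(tmm^2), rowSums(amm^2), "+") - 2 * tmm %*% t(amm))
  dmin <- apply(d, 1, min)
  inside <- ablation[tb] == 1
  signed <- ifelse(inside, dmin, -dmin)
  list(signed = signed, minMargin = max(0, min(signed)))
}

# concordant-pair AUC (ties count 1/2)
bruteAUC <- function(outcome, score) {
  x <- score[outcome == 1]; y <- score[outcome == 0]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# two-group log-rank by explicit observed-minus-expected enumeration
handLogrank <- function(group, times, events) {
  g <- as.integer(factor(group)) - 1L
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    atRisk <- times >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

# mask made of a few random spheres (anisotropic spacing honoured)
randomBlobMask <- function(shape, spacing, nSpheres = 3, rRange = c(4, 9),
                           seed = 1) {
  set.seed(seed)
  co <- ablamark:::coordArrays(shape, spacing)
  extent <- (shape - 1) * spacing
  a <- array(0, shape)
  for (i in seq_len(nSpheres)) {
    cen <- runif(3, 0.3, 0.7) * extent
    r <- runif(1, rRange[1], rRange[2])
    a[(co$Z - cen[1])^2 + (co$Y - cen[2])^2 + (co$X - cen[3])^2 <= r^2] <- 1
  }
  a
}

# sphere mask helper
sphereMask <- function(shape, spacing, center, radius) {
  co <- ablamark:::coordArrays(shape, spacing)
  Mask(array(as.numeric(
    (co$Z - center[1])^2 + (co$Y - center[2])^2 + (co$X - center[3])^2 <= radius^2
  ), shape), spacing)
}

smallPhantom <- function(seed = 3, breathing = 5, heating = 1.5) {
  makePhantomPair(phantomSpec(shape = c(16, 48, 48), spacing = c(5, 1, 1),
                              tumorRadius = 6, ablationRadius = 10,
                              breathingAmplitude = breathing,
                              heatingAmplitude = heating,
                              noiseSD = 0.01, seed = seed))
}

smallRegConfig <- function(...) {
  registrationConfig(mode = "3d", featureLevels = 3L, blockPartition = c(2, 3, 3),
                     controlSpacing = c(2, 8, 8), seed = 11, ...)
}

zeroDenseField <- function(shape) {
  f <- identityField(shape)
  f@dense <- array(0, c(shape, 3))
  f
}
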