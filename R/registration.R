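# Pairwise unsupervised deformable registration: a Siamese localizer
# proposes control-lattice displacements, the tent-kernel sampler warps the
# moving image, and the block-wise feature NCC loss is backpropagated through
# sampler and lattice to refine the field iteratively.

# ---- bending energy on the control lattice ---------------------------------

# sum of squared second differences along each lattice axis, per component
bendingEnergy <- function(phi) {
  e <- 0
  nd <- dim(phi)[1:3]
  for (ax in 1:3) {
    if (nd[ax] < 3L) next
    m <- aperm(phi, c(ax, setdiff(1:3, ax), 4))
    d2 <- m[-c(1, 2), , , , drop = FALSE] - 2 * m[-c(1, dim(m)[1]), , , , drop = FALSE] +
      m[-c(dim(m)[1] - 1, dim(m)[1]), , , , drop = FALSE]
    e <- e + sum(d2^2)
  }
  e
}

bendingGradient <- function(phi) {
  g <- array(0, dim(phi))
  nd <- dim(phi)[1:3]
  for (ax in 1:3) {
    n <- nd[ax]
    if (n < 3L) next
    perm <- c(ax, setdiff(1:3, ax), 4)
    m <- aperm(phi, perm)
    d2 <- m[-c(1, 2), , , , drop = FALSE] - 2 * m[-c(1, n), , , , drop = FALSE] +
      m[-c(n - 1, n), , , , drop = FALSE]
    gm <- array(0, dim(m))
    gm[1:(n - 2), , , ] <- gm[1:(n - 2), , , , drop = FALSE] + 2 * d2
    gm[2:(n - 1), , , ] <- gm[2:(n - 1), , , , drop = FALSE] - 4 * d2
    gm[3:n, , , ] <- gm[3:n, , , , drop = FALSE] + 2 * d2
    g <- g + aperm(gm, order(perm))
  }
  g
}

# ---- global translation initialiser ----------------------------------------

# NCC grid search for a uniform shift (voxels, z/y/x), coarse-to-fine on a
# stride-2 in-plane downsample.
translationSearch <- function(movN, fixN, maxShift = c(3, 6, 6)) {
  dims <- dim(movN)
  zstep <- if (dims[1] >= 32) 2 else 1
  zsub <- seq(1, dims[1], by = zstep)
  ysub <- seq(1, dims[2], by = 2); xsub <- seq(1, dims[3], by = 2)
  m2 <- movN[zsub, ysub, xsub]; f2 <- fixN[zsub, ysub, xsub]
  d2 <- dim(m2)
  toDS <- function(s) cbind(s[, 1] / zstep, s[, 2] / 2, s[, 3] / 2)
  coarse <- as.matrix(expand.grid(z = seq(-maxShift[1], maxShift[1], by = 1),
                                  y = seq(-maxShift[2], maxShift[2], by = 2),
                                  x = seq(-maxShift[3], maxShift[3], by = 2)))
  marg <- pmin(pmax(c(maxShift[1] / zstep, maxShift[2] / 2, maxShift[3] / 2) + 1, 2),
               floor((d2 - 2) / 2))
  ncc <- cppShiftNCC(as.numeric(m2), as.numeric(f2), d2, toDS(coarse),
                     as.integer(marg))
  best <- coarse[which.max(ncc), ]
  fine <- as.matrix(expand.grid(z = best[1] + seq(-0.75, 0.75, by = 0.25),
                                y = best[2] + seq(-1, 1, by = 0.5),
                                x = best[3] + seq(-1, 1, by = 0.5)))
  ncc2 <- cppShiftNCC(as.numeric(m2), as.numeric(f2), d2, toDS(fine),
                      as.integer(marg))
  as.numeric(fine[which.max(ncc2), ])
}

# ---- Siamese localizer ------------------------------------------------------

#' Siamese localization network
#'
#' Twin convolutional branches with shared (fixed, seeded) weights encode the
#' moving and fixed images into block-wise multiscale features; a final
#' linear regression head maps the concatenated pair encoding
#' (f_moving, f_fixed, f_moving - f_fixed) to the control-lattice
#' displacements. With the default zero-initialised head the proposal is the
#' identity field; a small seeded random head can be requested via
#' \code{headInit = "random"} in the config.
#'
#' @param moving,fixed geometry-matched \code{\linkS4class{Volume}}s
#' @param config a \code{\linkS4class{RegistrationConfig}}
#' @return a \code{\linkS4class{DisplacementField}} over the fixed geometry
#' @export
siameseLocalize <- function(moving, fixed, config = registrationConfig()) {
  checkGeometry(moving, fixed, "moving and fixed volumes")
  shape <- dim(fixed@data)
  nd <- latticeDims(shape, config@controlSpacing)
  fm <- as.vector(extractFeatures(moving, config)@blocks)
  fa <- as.vector(extractFeatures(fixed, config)@blocks)
  h <- c(fm, fa, fm - fa)
  npar <- prod(nd) * 3L
  phi <- if (config@headInit == "zero") {
    rep(0, npar)
  } else {
    H <- withSeed(config@seed + 1L,
                  matrix(stats::rnorm(npar * length(h),
                                      sd = 0.01 / sqrt(length(h))),
                         nrow = npar))
    as.numeric(H %*% h)
  }
  new("DisplacementField", control = array(phi, c(nd, 3)),
      controlSpacing = config@controlSpacing, dense = NULL,
      shape = as.integer(shape))
}

# ---- loss + gradient of a lattice state ------------------------------------

# Precompute everything reusable across iterations.
makeLossContext <- function(movN, fixN, config) {
  shape <- dim(movN)
  is3d <- config@mode == "3d"
  regions <- regionPartition(shape, config)
  checkRegionSize(regions, config)
  w <- makeConvWeights(config@seed, config@featureLevels, config@channelsBase,
                       is3d)
  fa <- lapply(regions, function(r) {
    ra <- regionArray(fixN, r, is3d)
    cppRegionFeatures(ra$arr, as.integer(ra$rdims), w, is3d)
  })
  faNorm <- vapply(fa, function(f) sqrt(sum(f^2)), 0)
  active <- faNorm > 1e-12
  if (!any(active)) stop("degenerate feature block: the fixed image yields ",
                         "zero-norm features in every region")
  if (any(!active) && !config@dropDegenerateBlocks)
    stop("degenerate feature block: ", sum(!active),
         " fixed-image regions have zero-norm features")
  nd <- latticeDims(shape, config@controlSpacing)
  list(shape = shape, is3d = is3d, regions = regions, weights = w, fa = fa,
       active = active, nd = nd, base = identityGrid(shape)@points,
       dims = as.integer(shape))
}

# Loss (feature NCC + bending energy) and its gradient wrt the lattice.
# Regions whose fixed-image features are degenerate are excluded up front;
# a warped region that collapses to zero norm contributes 0 (cosine treated
# as 0) with zero gradient, keeping the effective N constant across
# iterations.
latticeLossGrad <- function(phi, ctx, config, needGrad = TRUE) {
  dense <- cppLatticeToDense(phi, dim(phi)[1:3], ctx$dims,
                             config@controlSpacing)
  if (!ctx$is3d) dense[, , , 1] <- 0
  pts <- ctx$base
  pts[, "x"] <- pts[, "x"] + as.vector(dense[, , , 3])
  pts[, "y"] <- pts[, "y"] + as.vector(dense[, , , 2])
  pts[, "z"] <- pts[, "z"] + as.vector(dense[, , , 1])
  warped <- array(cppSamplePoints3D(as.numeric(attr(ctx, "mov")), ctx$dims, pts),
                  ctx$shape)
  featLoss <- 0
  dW <- if (needGrad) array(0, ctx$shape) else NULL
  for (i in seq_along(ctx$regions)) {
    if (!ctx$active[i]) next
    r <- ctx$regions[[i]]
    ra <- regionArray(warped, r, ctx$is3d)
    if (needGrad) {
      rl <- cppRegionLossGrad(ra$arr, as.integer(ra$rdims), ctx$weights,
                              ctx$fa[[i]], ctx$is3d)
      featLoss <- featLoss + rl$loss
      if (!rl$degenerate)
        dW[r$z, r$y, r$x] <- array(rl$grad, c(length(r$z), length(r$y),
                                              length(r$x)))
    } else {
      fw <- cppRegionFeatures(ra$arr, as.integer(ra$rdims), ctx$weights,
                              ctx$is3d)
      nw <- sqrt(sum(fw^2))
      if (nw > 1e-12)
        featLoss <- featLoss - sum(fw * ctx$fa[[i]]) /
          (nw * sqrt(sum(ctx$fa[[i]]^2)))
    }
  }
  loss <- featLoss + config@smoothnessWeight * bendingEnergy(phi)
  if (!is.finite(loss)) stop("optimization diverged: non-finite loss")
  if (!needGrad) return(list(loss = loss, warped = warped))
  g <- cppSampleGrad3D(as.numeric(attr(ctx, "mov")), ctx$dims, pts,
                       as.numeric(dW))
  dDense <- array(0, c(ctx$shape, 3))
  dDense[, , , 1] <- if (ctx$is3d) array(g[, 3], ctx$shape) else 0
  dDense[, , , 2] <- array(g[, 2], ctx$shape)
  dDense[, , , 3] <- array(g[, 1], ctx$shape)
  dPhi <- cppDenseGradToLattice(dDense, dim(phi)[1:3], ctx$dims,
                                config@controlSpacing) +
    config@smoothnessWeight * bendingGradient(phi)
  list(loss = loss, grad = dPhi, warped = warped)
}

# ---- the optimisation loop --------------------------------------------------

#' Register a moving image to a fixed image
#'
#' Unsupervised pairwise optimisation: the control-lattice displacements
#' proposed by \code{\link{siameseLocalize}} (optionally preceded by a global
#' NCC translation fit) are refined by gradient descent with momentum on the
#' block-wise feature NCC loss plus a bending-energy penalty, iterating
#' until the relative loss change drops below \code{tolerance} or the
#' iteration budget is exhausted. The best-loss state encountered is
#' returned (ties keep the earliest).
#'
#' @param moving,fixed geometry-matched \code{\linkS4class{Volume}}s with
#'   finite intensities; both are min-max normalised internally
#' @param config a \code{\linkS4class{RegistrationConfig}}
#' @return a \code{\linkS4class{RegistrationResult}}
#' @export
registerPair <- function(moving, fixed, config = registrationConfig()) {
  checkGeometry(moving, fixed, "moving and fixed volumes")
  movN <- normalize01(moving@data)
  fixN <- normalize01(fixed@data)
  ctx <- makeLossContext(movN, fixN, config)
  attr(ctx, "mov") <- movN
  shape <- ctx$shape

  phi <- siameseLocalize(moving, fixed, config)@control
  zeroPhi <- array(0, dim(phi))
  identityLoss <- latticeLossGrad(zeroPhi, ctx, config, needGrad = FALSE)$loss

  best <- list(loss = identityLoss, phi = zeroPhi)
  if (!identical(config@headInit, "zero")) {
    headLoss <- latticeLossGrad(phi, ctx, config, needGrad = FALSE)$loss
    if (headLoss < best$loss) best <- list(loss = headLoss, phi = phi)
    else phi <- best$phi
  }

  if (config@translationInit) {
    shift <- translationSearch(movN, fixN)
    if (!ctx$is3d) shift[1] <- 0
    if (any(shift != 0)) {
      phiT <- phi
      for (k in 1:3) phiT[, , , k] <- phiT[, , , k] + shift[k]
      tLoss <- latticeLossGrad(phiT, ctx, config, needGrad = FALSE)$loss
      if (tLoss < best$loss) {
        best <- list(loss = tLoss, phi = phiT)
        phi <- phiT
      }
    }
  }

  # Gradient descent with momentum; the gradient is scaled so that the first
  # step moves the lattice by learningRate voxels, and the step shrinks
  # (velocity reset) whenever the loss worsens — the usual regular-step
  # scheme for registration objectives.
  vel <- array(0, dim(phi))
  trace <- numeric(0)
  converged <- FALSE
  step <- config@learningRate
  for (it in seq_len(config@maxIters)) {
    lg <- tryCatch(latticeLossGrad(phi, ctx, config),
                   error = function(e) stop("optimization diverged at iteration ",
                                            it, ": ", conditionMessage(e)))
    trace <- c(trace, lg$loss)
    if (lg$loss < best$loss) best <- list(loss = lg$loss, phi = phi)
    if (it > 1L &&
        abs(trace[it] - trace[it - 1L]) <
        config@tolerance * max(abs(trace[it - 1L]), 1e-12)) {
      converged <- TRUE
      break
    }
    if (it > 1L && lg$loss > best$loss + 1e-12) {
      # overshoot: restart from the best state with a halved step; the next
      # iteration recomputes the gradient there
      step <- step / 2
      vel <- vel * 0
      phi <- best$phi
      if (step < config@learningRate / 256) { converged <- TRUE; break }
      next
    }
    gmax <- max(abs(lg$grad))
    if (gmax == 0) { converged <- TRUE; break }
    vel <- config@momentum * vel + lg$grad / gmax
    vmax <- max(abs(vel))
    if (vmax > 2) vel <- vel * (2 / vmax)
    phi <- phi - step * vel
  }

  field <- new("DisplacementField", control = best$phi,
               controlSpacing = config@controlSpacing, dense = NULL,
               shape = as.integer(shape))
  dense <- denseField(field, shape)
  if (!ctx$is3d) dense[, , , 1] <- 0
  field@dense <- dense
  warped <- trilinearSample(Volume(moving@data, fixed@spacing, fixed@origin),
                            fieldToGrid(field, shape))
  new("RegistrationResult", field = field, warped = warped,
      lossTrace = trace, iterations = length(trace), converged = converged,
      initialLoss = identityLoss)
}

#' Mean landmark registration error
#'
#' The field maps fixed-frame coordinates to moving-frame coordinates
#' (pull-back convention): each fixed-frame landmark p_f is sent to
#' p_f + u(p_f), and the error is the Euclidean mm distance to the true
#' moving-frame landmark.
#'
#' @param field a \code{\linkS4class{DisplacementField}} with a known shape
#' @param landmarks a \code{\linkS4class{LandmarkSet}} (world-mm, z/y/x)
#' @param spacing voxel spacing in mm (z, y, x)
#' @return list with \code{meanMM}, \code{sdMM} and \code{perLandmarkMM}
#' @export
landmarkError <- function(field, landmarks, spacing) {
  if (!is(landmarks, "LandmarkSet")) stop("landmarks must be a LandmarkSet")
  n <- nrow(landmarks@fixed)
  if (n < 1L) stop("empty landmark set")
  dense <- denseField(field)
  dims <- dim(dense)[1:3]
  vox <- sweep(landmarks@fixed, 2, spacing, "/")
  if (any(vox < -0.5) || any(sweep(vox, 2, dims - 0.5, ">")))
    stop("landmarks fall outside the image extent")
  pts <- cbind(x = vox[, 3], y = vox[, 2], z = vox[, 1])
  u <- vapply(1:3, function(k)
    cppSamplePoints3D(as.numeric(dense[, , , k]), as.integer(dims), pts),
    numeric(n))
  u <- matrix(u, nrow = n)
  pred <- landmarks@fixed + sweep(u, 2, spacing, "*")
  err <- sqrt(rowSums((pred - landmarks@moving)^2))
  list(meanMM = mean(err), sdMM = stats::sd(err), perLandmarkMM = err)
}
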