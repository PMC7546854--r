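# Synthetic phantom generator: geometry-true pre/post-ablation image pairs
# with a known deformation field and vessel landmarks. The phantom emulates a
# liver-like ellipsoid with bright vessel-like tubes, a hypointense tumour,
# and a post-ablation image produced by warping the pre-ablation image with a
# smooth "breathing" field (dominantly cranio-caudal, i.e. along the slice
# axis) plus a Gaussian-windowed radial "heating" contraction centred on the
# ablation zone, replacing the ablated region with a hyperintense zone.

#' Phantom specification
#'
#' @slot shape voxels (nz, ny, nx)
#' @slot spacing mm (z, y, x); the default 5 x 1 x 1 mirrors thick-slice
#'   abdominal acquisitions
#' @slot tumorCenter,tumorRadius mm (world frame); empty center = auto
#' @slot ablationCenter,ablationRadius mm; empty center places the ablation
#'   zone where the breathed tumour lands in the post image
#' @slot nVesselLandmarks landmarks sampled on vessel centerlines away from
#'   the ablation zone
#' @slot breathingAmplitude peak global smooth displacement in mm, dominant
#'   along z
#' @slot heatingAmplitude peak radial contraction in mm around the ablation
#'   center
#' @slot noiseSD additive Gaussian intensity noise (images are on a 0..1
#'   scale)
#' @slot seed RNG seed; all outputs are reproducible given the seed
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 tumorCenter = "numeric", tumorRadius = "numeric",
                 ablationCenter = "numeric", ablationRadius = "numeric",
                 nVesselLandmarks = "integer", breathingAmplitude = "numeric",
                 heatingAmplitude = "numeric", noiseSD = "numeric",
                 seed = "integer")
)

setValidity("PhantomSpec", function(object) {
  if (length(object@shape) != 3L || any(object@shape < 8L))
    return("shape must be 3 values, each >= 8 voxels")
  if (any(object@spacing <= 0)) return("spacing must be positive")
  if (object@tumorRadius <= 0 || object@ablationRadius <= 0)
    return("radii must be > 0")
  if (object@breathingAmplitude < 0 || object@heatingAmplitude < 0)
    return("amplitudes must be >= 0")
  if (object@noiseSD < 0) return("noiseSD must be >= 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults describe the study conditions the package is exercised under: a
#' 64 x 128 x 128 voxel volume at 5 x 1 x 1 mm, a 2.3-cm tumour inside a
#' 3.8-cm ablation zone, 6 mm of breathing motion and 2 mm of heating
#' contraction.
#'
#' @param shape,spacing volume geometry
#' @param tumorCenter,tumorRadius,ablationCenter,ablationRadius lesion
#'   geometry in mm; NULL centers are placed automatically
#' @param nVesselLandmarks,breathingAmplitude,heatingAmplitude,noiseSD,seed
#'   see the class slots
#' @export
phantomSpec <- function(shape = c(64, 128, 128), spacing = c(5, 1, 1),
                        tumorCenter = NULL, tumorRadius = 11.5,
                        ablationCenter = NULL, ablationRadius = 19,
                        nVesselLandmarks = 12L, breathingAmplitude = 6,
                        heatingAmplitude = 2, noiseSD = 0.02, seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape), spacing = as.numeric(spacing),
      tumorCenter = if (is.null(tumorCenter)) numeric(0) else as.numeric(tumorCenter),
      tumorRadius = tumorRadius,
      ablationCenter = if (is.null(ablationCenter)) numeric(0) else as.numeric(ablationCenter),
      ablationRadius = ablationRadius,
      nVesselLandmarks = as.integer(nVesselLandmarks),
      breathingAmplitude = breathingAmplitude,
      heatingAmplitude = heatingAmplitude, noiseSD = noiseSD,
      seed = as.integer(seed))
}

# world-mm coordinate arrays of every voxel center, order (z, y, x)
coordArrays <- function(shape, spacing) {
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  list(
    Z = array(rep((0:(nz - 1)) * spacing[1], times = ny * nx), shape),
    Y = array(rep(rep((0:(ny - 1)) * spacing[2], each = nz), times = nx), shape),
    X = array(rep((0:(nx - 1)) * spacing[3], each = nz * ny), shape)
  )
}

# analytic truth displacement (mm, fixed-frame -> moving-frame) at mm points;
# p is n x 3 (z, y, x) or a list of coordinate arrays
truthDisplacement <- function(Z, Y, X, extent, spec, ablationCenter) {
  bA <- spec@breathingAmplitude
  hA <- spec@heatingAmplitude
  uz <- bA * (0.75 + 0.25 * sin(pi * Z / extent[1])) *
    (0.9 + 0.1 * cos(pi * Y / extent[2]))
  uy <- 0.1 * bA * sin(pi * Y / extent[2])
  ux <- 0.1 * bA * sin(pi * X / extent[3])
  if (hA > 0 && length(ablationCenter) == 3L) {
    s <- spec@ablationRadius
    rz <- Z - ablationCenter[1]; ry <- Y - ablationCenter[2]
    rx <- X - ablationCenter[3]
    r <- sqrt(rz^2 + ry^2 + rx^2)
    g <- hA * (r / s) * exp((1 - (r / s)^2) / 2) / pmax(r, 1e-9)
    uz <- uz + g * rz; uy <- uy + g * ry; ux <- ux + g * rx
  }
  list(uz = uz, uy = uy, ux = ux)
}

truthAt <- function(p, extent, spec, ablationCenter) {
  u <- truthDisplacement(p[, 1], p[, 2], p[, 3], extent, spec, ablationCenter)
  cbind(u$uz, u$uy, u$ux)
}

# invert p_f + u(p_f) = p_m for p_f by fixed-point iteration
invertTruth <- function(pm, extent, spec, ablationCenter, iters = 12L) {
  pf <- pm
  for (i in seq_len(iters)) pf <- pm - truthAt(pf, extent, spec, ablationCenter)
  pf
}

#' Generate a pre/post-ablation phantom pair with ground truth
#'
#' @param spec a \code{\linkS4class{PhantomSpec}}
#' @return list with elements \code{moving}, \code{fixed}
#'   (\code{\linkS4class{Volume}}s), \code{tumor} (mask, moving frame),
#'   \code{ablation} (mask, fixed frame), \code{truthField}
#'   (\code{\linkS4class{DisplacementField}}, fixed-to-moving pull-back in
#'   voxel units) and \code{landmarks} (\code{\linkS4class{LandmarkSet}})
#' @export
makePhantomPair <- function(spec = phantomSpec()) {
  shape <- spec@shape; sp <- spec@spacing
  extent <- (shape - 1) * sp
  withSeed(spec@seed, {
    co <- coordArrays(shape, sp)
    cent <- extent / 2
    semi <- c(0.42, 0.38, 0.42) * extent
    ell <- ((co$Z - cent[1]) / semi[1])^2 + ((co$Y - cent[2]) / semi[2])^2 +
      ((co$X - cent[3]) / semi[3])^2
    moving <- array(0, shape)
    moving[ell <= 1] <- 0.45

    # vessel-like bright tubes: random chords inside the shrunken ellipsoid
    nseg <- 8L
    rpt <- function() {
      repeat {
        p <- cent + stats::runif(3, -1, 1) * semi * 0.75
        if (sum(((p - cent) / (semi * 0.75))^2) <= 1) return(p)
      }
    }
    segs <- lapply(seq_len(nseg), function(i) list(a = rpt(), b = rpt()))
    vrad <- 1.8
    for (s in segs) {
      lo <- pmax(pmin(s$a, s$b) - vrad - 2 * sp, 0)
      hi <- pmin(pmax(s$a, s$b) + vrad + 2 * sp, extent)
      iz <- which((0:(shape[1] - 1)) * sp[1] >= lo[1] & (0:(shape[1] - 1)) * sp[1] <= hi[1])
      iy <- which((0:(shape[2] - 1)) * sp[2] >= lo[2] & (0:(shape[2] - 1)) * sp[2] <= hi[2])
      ix <- which((0:(shape[3] - 1)) * sp[3] >= lo[3] & (0:(shape[3] - 1)) * sp[3] <= hi[3])
      if (!length(iz) || !length(iy) || !length(ix)) next
      Zb <- co$Z[iz, iy, ix]; Yb <- co$Y[iz, iy, ix]; Xb <- co$X[iz, iy, ix]
      ab <- s$b - s$a
      len2 <- sum(ab^2)
      t <- ((Zb - s$a[1]) * ab[1] + (Yb - s$a[2]) * ab[2] + (Xb - s$a[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      dz <- Zb - (s$a[1] + t * ab[1]); dy <- Yb - (s$a[2] + t * ab[2])
      dx <- Xb - (s$a[3] + t * ab[3])
      tube <- sqrt(dz^2 + dy^2 + dx^2) <= vrad
      blk <- moving[iz, iy, ix]
      blk[tube & blk > 0] <- 0.9
      moving[iz, iy, ix] <- blk
    }

    tc <- if (length(spec@tumorCenter) == 3L) spec@tumorCenter
          else cent + c(0.15, 0.12, -0.10) * semi
    if (sum(((tc - cent) / semi)^2) > 1)
      stop("phantom spec error: tumor center falls outside the liver ellipsoid")
    tumorDist <- sqrt((co$Z - tc[1])^2 + (co$Y - tc[2])^2 + (co$X - tc[3])^2)
    moving[tumorDist <= spec@tumorRadius] <- 0.2
    tumorMask <- array(as.numeric(tumorDist <= spec@tumorRadius), shape)

    # place the ablation zone where the breathed tumour center lands
    ac <- if (length(spec@ablationCenter) == 3L) spec@ablationCenter
          else as.numeric(invertTruth(matrix(tc, 1), extent, spec, numeric(0)))
    if (any(ac - spec@ablationRadius < -sp) || any(ac + spec@ablationRadius > extent + sp))
      stop("phantom spec error: ablation zone falls outside the image")

    u <- truthDisplacement(co$Z, co$Y, co$X, extent, spec, ac)
    dense <- array(0, c(shape, 3))
    dense[, , , 1] <- u$uz / sp[1]
    dense[, , , 2] <- u$uy / sp[2]
    dense[, , , 3] <- u$ux / sp[3]
    truthField <- new("DisplacementField", control = array(0, c(0, 0, 0, 3)),
                      controlSpacing = c(1, 1, 1), dense = dense,
                      shape = shape)

    fixed <- volData(trilinearSample(Volume(moving, sp),
                                     fieldToGrid(truthField, shape)))
    ablDist <- sqrt((co$Z - ac[1])^2 + (co$Y - ac[2])^2 + (co$X - ac[3])^2)
    ablMask <- array(as.numeric(ablDist <= spec@ablationRadius), shape)
    fixed[ablMask == 1] <- 0.85

    if (spec@noiseSD > 0) {
      moving <- moving + stats::rnorm(length(moving), sd = spec@noiseSD)
      fixed <- fixed + stats::rnorm(length(fixed), sd = spec@noiseSD)
    }

    # landmarks on vessel centerlines, away from the ablation zone
    cand <- do.call(rbind, lapply(segs, function(s) {
      t <- seq(0.08, 0.92, length.out = 25)
      cbind(s$a[1] + t * (s$b[1] - s$a[1]), s$a[2] + t * (s$b[2] - s$a[2]),
            s$a[3] + t * (s$b[3] - s$a[3]))
    }))
    pf <- invertTruth(cand, extent, spec, ac)
    distAc <- sqrt(rowSums(sweep(pf, 2, ac)^2))
    inExtent <- pf[, 1] > 2 * sp[1] & pf[, 1] < extent[1] - 2 * sp[1] &
      pf[, 2] > 2 * sp[2] & pf[, 2] < extent[2] - 2 * sp[2] &
      pf[, 3] > 2 * sp[3] & pf[, 3] < extent[3] - 2 * sp[3]
    for (fac in c(2.2, 1.8, 1.5, 1.2, 1.05)) {
      ok <- which(inExtent & distAc > fac * spec@ablationRadius)
      if (length(ok) >= spec@nVesselLandmarks) break
    }
    if (length(ok) < 1L) stop("phantom spec error: no valid landmark sites")
    pick <- ok[round(seq(1, length(ok),
                         length.out = min(spec@nVesselLandmarks, length(ok))))]
    landmarks <- LandmarkSet(moving = cand[pick, , drop = FALSE],
                             fixed = pf[pick, , drop = FALSE])

    list(moving = Volume(moving, sp), fixed = Volume(fixed, sp),
         tumor = Mask(tumorMask, sp), ablation = Mask(ablMask, sp),
         truthField = truthField, landmarks = landmarks)
  })
}
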